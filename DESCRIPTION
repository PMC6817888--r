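Package: dpdshear
Title: Dissipative Particle Dynamics of Phospholipid Assemblies Under
    Reverse Non-Equilibrium Shear
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A coarse-grained dissipative particle dynamics (DPD) engine for
    double-tailed phospholipids in explicit water, with steady shear imposed
    by the reverse non-equilibrium momentum-swap (Mueller-Plathe) method.
    Builds solvated lipid boxes and idealized porous-cylinder initial states,
    integrates the soft conservative/dissipative/random pair forces with the
    modified velocity Verlet scheme under NVT conditions, and computes the
    standard structural and dynamic observables: per-chain gyration tensors,
    radius of gyration and shape factor (relative asphericity), slab velocity
    profiles and shear rates, momentum-flux bookkeeping, and energy traces
    with plateau detection. Results are returned as tibbles with broom-style
    tidiers and ggplot2 plotting methods.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
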