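Package: photofate
Title: Photochemical Fate of Contaminants in Sunlit Surface Waters
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state modelling of the photochemical transformation of
    dissolved contaminants in sunlit freshwaters. Computes formation and
    scavenging budgets of the photogenerated transients (hydroxyl radical,
    carbonate radical, singlet oxygen and excited triplet states of
    chromophoric dissolved organic matter), pathway-resolved pseudo-first-order
    degradation rate constants and half-lives, and intermediate formation
    kinetics, from spectral photon-flux, water-chemistry and compound
    photoreactivity inputs. Also provides the laboratory-kinetics fitting
    procedures used to measure photoreactivity parameters (quantum yields,
    competition kinetics, probe-based rate-constant determination,
    back-reduction), screening-level QSAR estimators of second-order rate
    constants from the one-electron oxidation potential, and scenario
    extensions for pH speciation, stratified lakes, rivers and evaporative
    concentration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
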