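#' Built-in E. coli core subnetworks
#'
#' Returns one of the packaged subnetworks of the E. coli core metabolic
#' model, together with its boundary-condition presets. Available fixtures:
#' `"glycolysis_ppp"` (upper glycolysis + pentose phosphate, 13 reactions),
#' `"glycolysis"`, `"tca"` (TCA cycle with pyruvate dehydrogenase and
#' pyruvate formate lyase), `"nadtrhd"` (transhydrogenase), `"etc"`
#' (electron transport chain), `"atp_synthase"`, and `"respiration"` — the
#' modular composition of glycolysis, TCA, transhydrogenase, electron
#' transport chain and ATP synthase over their shared species.
#'
#' Reaction directions follow the source model except that RPI is oriented
#' `RU5P <-> R5P` and SUCOAS `ADP + PI + SUCCOA <-> ATP + COA + SUCC`, and
#' the cytochrome oxidase reaction is doubled to clear its half-integer
#' oxygen coefficient; all three choices keep the packaged pathway analyses
#' in exact integer form.
#'
#' @param name fixture name.
#' @return list with elements `network` (a
#'   [StoichiometricNetwork-class]) and `presets` (chemostat/flowstat
#'   sets).
#' @examples
#' fx <- makeFixture("glycolysis_ppp")
#' nReactions(fx$network)
#' @export
makeFixture <- function(name = c("glycolysis_ppp", "glycolysis", "tca",
                                 "nadtrhd", "etc", "atp_synthase",
                                 "respiration")) {
    name <- match.arg(name)
    presets <- yaml::read_yaml(.fixtureFile("presets.yaml"))
    if (name == "respiration") {
        parts <- c("glycolysis", "tca", "nadtrhd", "etc", "atp_synthase")
        common <- presets$respiration$common_species
        mods <- lapply(parts, function(p) {
            net <- loadModel(.fixtureFile(paste0(p, ".txt")),
                             format = "reaction_list")
            m <- networkModule(net, name = p)
            exposeSpecies(m, intersect(common, speciesIds(net)))
        })
        net <- composeModules(mods, common = common)
        return(list(network = net, presets = presets$respiration))
    }
    net <- loadModel(.fixtureFile(paste0(name, ".txt")),
                     format = "reaction_list")
    list(network = net, presets = presets[[name]])
}

.fixtureFile <- function(fname) {
    path <- system.file("extdata", fname, package = "BondGraphMet")
    if (!nzchar(path)) stop("fixture file not found: ", fname)
    path
}

#' List the packaged fixtures
#'
#' @return character vector of fixture names.
#' @export
listFixtures <- function() {
    c("glycolysis_ppp", "glycolysis", "tca", "nadtrhd", "etc",
      "atp_synthase", "respiration")
}

# run expr under a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(list = ".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

#' Random connected integer reaction network
#'
#' Generates a sparse integer stoichiometric network: a backbone of
#' reactions chaining consecutive species guarantees connectivity, and the
#' remaining reactions connect random reactant/product pairs. Every
#' reaction has at least one reactant and one product; coefficients are
#' drawn from `1:maxCoeff`. Reproducible under `seed`.
#'
#' @param nSpecies,nReactions network size (`nReactions >= nSpecies - 1`
#'   so the backbone can reach every species).
#' @param maxCoeff largest stoichiometric coefficient.
#' @param seed RNG seed.
#' @return A [StoichiometricNetwork-class].
#' @export
randomNetwork <- function(nSpecies, nReactions, maxCoeff = 2, seed = 1) {
    stopifnot(nSpecies >= 1, nReactions >= 1, maxCoeff >= 1)
    if (nSpecies > 1 && nReactions < nSpecies - 1)
        stop("need at least nSpecies - 1 reactions for a connected network")
    .withSeed(seed, {
        sid <- sprintf("S%d", seq_len(nSpecies))
        rx <- list()
        for (j in seq_len(nReactions)) {
            if (nSpecies == 1) {
                sub <- 1; prod <- 1
            } else if (j < nSpecies) {
                sub <- j; prod <- j + 1
            } else {
                sub <- sample.int(nSpecies, 1)
                prod <- sample(setdiff(seq_len(nSpecies), sub), 1)
            }
            st <- stats::setNames(
                c(-sample.int(maxCoeff, length(sub), replace = TRUE),
                  sample.int(maxCoeff, length(prod), replace = TRUE)),
                sid[c(sub, prod)])
            # occasionally add a third participant
            if (nSpecies > 2 && stats::runif(1) < 0.3) {
                extra <- sample(setdiff(seq_len(nSpecies), c(sub, prod)), 1)
                st <- c(st, stats::setNames(
                    sample(c(-1, 1), 1) * sample.int(maxCoeff, 1),
                    sid[extra]))
            }
            rx[[sprintf("r%d", j)]] <- st
        }
        stoichiometricNetwork(rx, species = sid)
    })
}

#' Synthetic steady-state dataset with known ground truth
#'
#' Emulates a steady-state measurement campaign: assigns the supplied
#' species constants and mass-action constants, simulates to steady state
#' under the given chemostats, and emits the reaction potentials, fluxes
#' and concentrations a measurement would see. Potentials get additive
#' Gaussian noise (sd `noiseSd` mV, they are signed); fluxes and
#' concentrations get multiplicative log-normal noise (sd `noiseSd` on the
#' log scale, they are positive). A fraction `missingFrac` of flux and
#' concentration entries is masked at random and the potentials of
#' `unknownPhi` reactions are marked unknown. All draws are reproducible
#' under `seed`.
#'
#' @param net a [StoichiometricNetwork-class].
#' @param K,kappa named true parameter vectors.
#' @param chemostats named numeric vector of fixed amounts (or character
#'   vector using stored `x0`).
#' @param flowstats passed to [simulateNetwork()].
#' @param noiseSd noise level (0 = exact data).
#' @param missingFrac fraction of flux/concentration entries masked.
#' @param unknownPhi reaction ids whose potentials are reported unknown.
#' @param seed RNG seed.
#' @param tMax steady-state search horizon.
#' @param temperature kelvin.
#' @return list with `data` (a [SteadyStateData-class]) and `truth`
#'   (list: `phi`, `Phi`, `f`, `c`, `K`, `kappa`).
#' @export
generateDataset <- function(net, K, kappa, chemostats = character(),
                            flowstats = character(), noiseSd = 0,
                            missingFrac = 0, unknownPhi = character(),
                            seed = 1, tMax = 1e5, temperature = 310) {
    net <- setSpeciesConstants(net, K)
    net <- setMassAction(net, kappa)
    traj <- simulateNetwork(net, chemostats = chemostats,
                            flowstats = flowstats, tEnd = 10,
                            untilSteady = TRUE, tMax = tMax,
                            temperature = temperature)
    if (!traj@steady)
        stop("no steady state reached within tMax = ", tMax)
    n <- length(traj@time)
    xss <- traj@x[n, ]
    fss <- traj@f[n, ]
    phi <- traj@phi[n, ]
    Phi <- traj@Phi[n, ]
    .withSeed(seed, {
        PhiObs <- Phi + stats::rnorm(length(Phi), 0, noiseSd)
        fObs <- fss * exp(stats::rnorm(length(fss), 0, noiseSd))
        cObs <- xss * exp(stats::rnorm(length(xss), 0, noiseSd))
        PhiObs[names(PhiObs) %in% unknownPhi] <- NA_real_
        if (missingFrac > 0) {
            fObs[stats::runif(length(fObs)) < missingFrac] <- NA_real_
            cObs[stats::runif(length(cObs)) < missingFrac] <- NA_real_
        }
        list(data = steadyStateData(PhiObs, fObs, cObs),
             truth = list(phi = phi, Phi = Phi, f = fss, c = xss,
                          K = stats::setNames(net@species$K,
                                              speciesIds(net)),
                          kappa = stats::setNames(net@reactions$kappa,
                                                  reactionIds(net))))
    })
}
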