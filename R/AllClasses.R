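#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' StoichiometricNetwork: species, reactions and the stoichiometric matrix
#'
#' The central container of the package. Holds an ordered species table, an
#' ordered reaction table and the integer stoichiometric matrix `N`
#' (species x reactions). Column `j` of `N` is the signed stoichiometry of
#' reaction `j`; `N = Nr - Nf` where `Nf` collects the (positive) reactant
#' coefficients and `Nr` the product coefficients.
#'
#' Species carry the thermodynamic species constant `K` (> 0) and an amount
#' `x0` used as the default initial state; reactions carry a rate-law tag
#' (`"mass_action"` or `"michaelis_menten"`) and its parameters. Chemostat
#' and flowstat flags mark boundary conditions.
#'
#' @slot species data.frame with columns `id`, `name`, `K`, `x0`,
#'   `chemostat`.
#' @slot reactions data.frame with columns `id`, `kinetics`, `kappa`,
#'   `fmax`, `Kf`, `rho`, `flowstat`, `flowstatValue`.
#' @slot stoich integer matrix, rows named by species id, columns by
#'   reaction id.
#' @aliases StoichiometricNetwork
#' @export
setClass("StoichiometricNetwork",
    representation(species = "data.frame",
                   reactions = "data.frame",
                   stoich = "matrix"))

setValidity("StoichiometricNetwork", function(object) {
    sp <- object@species
    rx <- object@reactions
    N <- object@stoich
    msg <- character()
    need.sp <- c("id", "name", "K", "x0", "chemostat")
    need.rx <- c("id", "kinetics", "kappa", "fmax", "Kf", "rho",
                 "flowstat", "flowstatValue")
    if (!all(need.sp %in% names(sp)))
        msg <- c(msg, "species table lacks required columns")
    if (!all(need.rx %in% names(rx)))
        msg <- c(msg, "reaction table lacks required columns")
    if (length(msg)) return(msg)
    if (anyDuplicated(sp$id)) msg <- c(msg, "duplicate species ids")
    if (anyDuplicated(rx$id)) msg <- c(msg, "duplicate reaction ids")
    if (nrow(N) != nrow(sp) || ncol(N) != nrow(rx))
        msg <- c(msg, "stoichiometric matrix dimensions disagree with tables")
    else {
        if (nrow(sp) && !identical(rownames(N), sp$id))
            msg <- c(msg, "row names of N must equal species ids")
        if (nrow(rx) && !identical(colnames(N), rx$id))
            msg <- c(msg, "column names of N must equal reaction ids")
    }
    if (any(N != round(N)))
        msg <- c(msg, "stoichiometric matrix must be integer-valued")
    bad <- !is.na(sp$K) & sp$K <= 0
    if (any(bad))
        msg <- c(msg, paste0("species constant K must be positive: ",
                             paste(sp$id[bad], collapse = ", ")))
    if (any(!is.na(sp$x0) & sp$x0 < 0))
        msg <- c(msg, "species amounts must be nonnegative")
    if (!all(rx$kinetics %in% c("mass_action", "michaelis_menten")))
        msg <- c(msg, "unknown kinetics tag")
    if (any(!is.na(rx$kappa) & rx$kappa <= 0))
        msg <- c(msg, "reaction constant kappa must be positive")
    if (any(!is.na(rx$rho) & (rx$rho <= 0 | rx$rho >= 1)))
        msg <- c(msg, "rho must lie strictly between 0 and 1")
    if (length(msg)) msg else TRUE
})

#' BondGraph: typed components and bonds
#'
#' Species are stored by `Ce` components (one per species, attached to a `0`
#' junction), reactions by dissipating `Re` components flanked by two `1`
#' junctions. Stoichiometric coefficients with magnitude above one are
#' represented as an integer bond weight rather than duplicated bonds.
#'
#' @slot components data.frame with columns `id`, `type`
#'   (`Ce`/`Re`/`J0`/`J1`), `ref` (species or reaction id, NA for
#'   junctions).
#' @slot bonds data.frame with columns `tail`, `head`, `weight` and `port`
#'   (`"f"`/`"r"` for Re ports, NA otherwise).
#' @slot species,reactions parameter tables carried over from the source
#'   network so the graph is self-contained.
#' @export
setClass("BondGraph",
    representation(components = "data.frame",
                   bonds = "data.frame",
                   species = "data.frame",
                   reactions = "data.frame"))

setValidity("BondGraph", function(object) {
    cmp <- object@components
    bnd <- object@bonds
    msg <- character()
    if (!all(c("id", "type", "ref") %in% names(cmp)))
        return("components table lacks required columns")
    if (!all(c("tail", "head", "weight", "port") %in% names(bnd)))
        return("bonds table lacks required columns")
    if (anyDuplicated(cmp$id)) msg <- c(msg, "duplicate component ids")
    if (!all(cmp$type %in% c("Ce", "Re", "J0", "J1")))
        msg <- c(msg, "unknown component type")
    if (nrow(bnd) && !all(c(bnd$tail, bnd$head) %in% cmp$id))
        msg <- c(msg, "bond endpoint not a component")
    if (any(bnd$weight < 1 | bnd$weight != round(bnd$weight)))
        msg <- c(msg, "bond weights must be positive integers")
    if (length(msg)) msg else TRUE
})

#' NetworkModule: a network with exposed port species
#'
#' A module wraps a [StoichiometricNetwork-class] together with the set of
#' species exposed as ports for composition. Any species can be exposed;
#' composition unifies equally named exposed species across modules.
#'
#' @slot name module name, used to prefix private species on collision.
#' @slot network the wrapped network.
#' @slot exposed character vector of exposed species ids.
#' @export
setClass("NetworkModule",
    representation(name = "character",
                   network = "StoichiometricNetwork",
                   exposed = "character"))

setValidity("NetworkModule", function(object) {
    if (!all(object@exposed %in% object@network@species$id))
        "exposed species not present in module network"
    else TRUE
})

#' PathwayDecomposition: null-space pathways under chemostats/flowstats
#'
#' @slot chemostats,flowstats the boundary-condition id sets.
#' @slot Ncd constrained stoichiometric matrix (chemostat rows and flowstat
#'   columns zeroed).
#' @slot Kp integer pathway basis (reactions x pathways); each column has
#'   coprime entries, zero rows at flowstatted reactions, and sign fixed so
#'   its first nonzero entry is positive.
#' @slot Np pathway stoichiometry `N Kp`.
#' @slot types per-pathway label `"I"`, `"II"` or `"III"` (or NA when not
#'   classified).
#' @slot fp optional estimated pathway flows.
#' @export
setClass("PathwayDecomposition",
    representation(chemostats = "character",
                   flowstats = "character",
                   Ncd = "matrix",
                   Kp = "matrix",
                   Np = "matrix",
                   types = "character",
                   fp = "numericOrNULL"))

setValidity("PathwayDecomposition", function(object) {
    msg <- character()
    if (ncol(object@Kp) != ncol(object@Np))
        msg <- c(msg, "Kp and Np must have the same number of pathways")
    if (any(object@Ncd %*% object@Kp != 0))
        msg <- c(msg, "Kp is not in the null space of Ncd")
    if (length(msg)) msg else TRUE
})

#' SteadyStateData: measurements at a steady state
#'
#' Reaction potentials are stored for all reactions with `NA` marking the
#' unknown subset (defining the known/unknown column partition of `N`);
#' fluxes and concentrations use `NA` for missing values. All quantities are
#' normalized (see [normalizeData()]): concentrations by `c0`, flows by
#' `f0`, time by `t0 = c0/f0`; potentials are in mV.
#'
#' @slot Phi named reaction potentials (mV), NA = unknown.
#' @slot f named reaction fluxes (normalized), NA = missing.
#' @slot c named species concentrations (normalized), NA = missing.
#' @slot normalization list with elements `c0` (mM), `f0` (mM/s), `t0` (s).
#' @export
setClass("SteadyStateData",
    representation(Phi = "numeric",
                   f = "numeric",
                   c = "numeric",
                   normalization = "list"))

#' PotentialEstimate: QP estimate of species potentials
#'
#' @slot phi estimated species potentials (mV).
#' @slot Phi0hat,Phi1hat estimated reaction potentials for the known and
#'   unknown partitions.
#' @slot residual per-reaction residual `Phi0hat - Phi0` (mV).
#' @slot active logical flags over the unknown reactions: constraint active.
#' @slot kkt KKT residual of the QP solution.
#' @export
setClass("PotentialEstimate",
    representation(phi = "numeric",
                   Phi0hat = "numeric",
                   Phi1hat = "numeric",
                   residual = "numeric",
                   active = "logical",
                   kkt = "numeric"))

#' EbaReport: energy-balance diagnostics of a flux/potential pair
#'
#' @slot r per-reaction flux resistances `Phi_i / f_i` (positive when the
#'   sign constraint holds; `Inf` flags zero flow at nonzero potential).
#' @slot cycleResidual max-norm of `K' Phi` over the closed-system cycle
#'   basis `K`.
#' @slot pathwayResidual max-norm of `K' R Kp fp` (NA when `fp` absent).
#' @slot violations ids of reactions with `f_i * Phi_i < 0`.
#' @export
setClass("EbaReport",
    representation(r = "numeric",
                   cycleResidual = "numeric",
                   pathwayResidual = "numeric",
                   violations = "character"))

#' ParameterSet: estimated thermodynamically safe parameters
#'
#' @slot phi estimated species potentials (mV).
#' @slot K species constants (per species; NA when the concentration was
#'   missing).
#' @slot kappa mass-action reaction constants.
#' @slot f estimated reaction fluxes.
#' @slot fp estimated pathway flows.
#' @slot mm optional data.frame of reversible Michaelis-Menten triples
#'   (`fmax`, `rho`, `Kf`) and their mass-action equivalents `kappa1`,
#'   `kappa2`.
#' @export
setClass("ParameterSet",
    representation(phi = "numeric",
                   K = "numeric",
                   kappa = "numeric",
                   f = "numeric",
                   fp = "numeric",
                   mm = "ANY"))

#' Trajectory: result of a dynamic simulation
#'
#' @slot time time grid (normalized units).
#' @slot x species amounts (time x species).
#' @slot f reaction flows (time x reactions).
#' @slot exchange external (chemostat-balancing) flows `N f` (time x
#'   species).
#' @slot phi,Phi species and reaction potentials along the trajectory.
#' @slot steady TRUE when the terminal state met the steady-state test.
#' @slot chemostats,flowstats the boundary conditions used.
#' @export
setClass("Trajectory",
    representation(time = "numeric",
                   x = "matrix",
                   f = "matrix",
                   exchange = "matrix",
                   phi = "matrix",
                   Phi = "matrix",
                   steady = "logical",
                   chemostats = "character",
                   flowstats = "character"))
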