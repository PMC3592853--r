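#' Build a simulation scenario from a named preset
#'
#' Presets encode the study conditions of basal and insulin-stimulated
#' adipocytes, each with an ATP-depleted (`_kcn`) variant in which
#' endocytosis is abolished (Ke = 0) and directed motion absent:
#'
#' \describe{
#'   \item{basal}{Kd = 0.12, Ke = 0.57 min^-1, DFree = 0.092 µm^2/s,
#'     stationary clustered fraction 48\%.}
#'   \item{insulin}{Kd = 0.31, Ke = 0.34 min^-1, stationary clustered
#'     fraction 27\%.}
#'   \item{basal_kcn / insulin_kcn}{as above with Ke = 0.}
#'   \item{custom}{basal values, every field overridable.}
#' }
#'
#' The association rate Ka is set by detailed balance to the preset's
#' stationary clustered fraction f: Ka = Kd f / (1 - f). The bleaching
#' rate at full illumination defaults to 2 min^-1 so that bleaching
#' dominates disappearance at p = 1, which is what makes the
#' relative-exposure extrapolation necessary. Cluster diameters default to
#' 170 x 90 nm (mean) with 30 nm spread; localization noise to 30 nm per
#' coordinate.
#'
#' @param preset one of `"basal"`, `"insulin"`, `"basal_kcn"`,
#'   `"insulin_kcn"`, `"custom"`.
#' @param ... named overrides of any [ScenarioConfig-class] slot
#'   (e.g. `nMolecules = 500`, `clusterDensity = 0`).
#' @return A validated [ScenarioConfig-class].
#' @examples
#' cfg <- makeScenario("basal", nMolecules = 100)
#' cfg@Kd   # 0.12 min^-1
#' @export
makeScenario <- function(preset = c("basal", "insulin", "basal_kcn",
                                    "insulin_kcn", "custom"), ...) {
    preset <- match.arg(preset)
    base <- list(
        preset = preset,
        DFree = 0.092, DIn = 0.092,
        Kd = 0.12, Ke = 0.57, Kb = 2,
        Ka = NA_real_, pCapture = 1,
        clusterDensity = 0.3,
        clusterMajor = 170, clusterMinor = 90, clusterAxisSD = 30,
        fieldSize = c(10, 10), nMolecules = 200L,
        blinkOffProb = 0.05, blinkMaxGap = 3L,
        sigmaLoc = 30, fClustered0 = 0.48,
        association = "rate", seed = 1L)
    if (preset %in% c("insulin", "insulin_kcn")) {
        base$Kd <- 0.31; base$Ke <- 0.34; base$fClustered0 <- 0.27
    }
    if (preset %in% c("basal_kcn", "insulin_kcn")) base$Ke <- 0
    over <- list(...)
    unknown <- setdiff(names(over), c(names(base)))
    if (length(unknown))
        stop("unknown scenario fields: ", paste(unknown, collapse = ", "))
    base[names(over)] <- over
    if (is.na(base$Ka))
        base$Ka <- base$Kd * base$fClustered0 / (1 - base$fClustered0)
    new("ScenarioConfig",
        preset = base$preset,
        DFree = base$DFree, DIn = base$DIn,
        Kd = base$Kd, Ke = base$Ke, Kb = base$Kb, Ka = base$Ka,
        pCapture = base$pCapture, clusterDensity = base$clusterDensity,
        clusterMajor = base$clusterMajor, clusterMinor = base$clusterMinor,
        clusterAxisSD = base$clusterAxisSD,
        fieldSize = as.numeric(base$fieldSize),
        nMolecules = as.integer(base$nMolecules),
        blinkOffProb = base$blinkOffProb,
        blinkMaxGap = as.integer(base$blinkMaxGap),
        sigmaLoc = base$sigmaLoc, fClustered0 = base$fClustered0,
        association = base$association, seed = as.integer(base$seed))
}

#' Evanescent-field intensity ratio between two excitation wavelengths
#'
#' In objective-type TIRF the evanescent intensity decays as
#' \eqn{I_\lambda(z) = I_0 \exp(-z/\delta(\lambda))} with penetration depth
#' approximately proportional to wavelength, \eqn{\delta(\lambda) =
#' \delta_{ref}\,\lambda/\lambda_b}. The ratio \eqn{I_b(z)/I_a(z)}
#' quantifies how much more steeply a shorter activation wavelength decays
#' than the imaging wavelength, i.e. how selectively molecules at the
#' coverslip are photoactivated. At \eqn{z = \delta(\lambda_b)} the ratio
#' reduces to \eqn{\exp(1 - \lambda_a/\lambda_b)}.
#'
#' @param z depth above the interface, nm.
#' @param lambdaA,lambdaB the two wavelengths, nm (A the activation,
#'   B the reference whose penetration depth is known).
#' @param deltaRef penetration depth at `lambdaB`, nm.
#' @return the intensity ratio I_B(z) / I_A(z).
#' @examples
#' evanescentRatio(100, 405, 488, deltaRef = 100)  # exp(1 - 405/488)
#' @export
evanescentRatio <- function(z, lambdaA, lambdaB, deltaRef = 100) {
    if (any(c(lambdaA, lambdaB, deltaRef) <= 0) || any(z < 0))
        stop("wavelengths and penetration depth must be positive, z >= 0")
    dA <- deltaRef * lambdaA / lambdaB
    dB <- deltaRef
    exp(-z / dB) / exp(-z / dA)
}

#' Diameter of the flat cluster formed by a fully flattened vesicle
#'
#' Area-conservation model of cluster nucleation by vesicle fusion: the
#' whole membrane of a spherical storage vesicle of diameter `Dgsv`
#' (surface area \eqn{\pi D_{GSV}^2}) flattens into the plasma membrane as
#' a disc of area \eqn{\tfrac14 \pi D_{cluster}^2}, giving
#' \eqn{D_{cluster} = 2 D_{GSV}}.
#'
#' @param Dgsv vesicle diameter, nm.
#' @return cluster diameter, nm.
#' @examples
#' flattenedVesicleDiameter(50)  # 100 nm
#' @export
flattenedVesicleDiameter <- function(Dgsv) {
    if (!is.numeric(Dgsv) || any(!is.finite(Dgsv)) || any(Dgsv <= 0))
        stop("Dgsv must be positive")
    2 * Dgsv
}
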