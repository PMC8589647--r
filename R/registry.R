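#' Feature registry for the 77-feature analysis matrix
#'
#' The analysis matrix holds 77 hemisphere-averaged FreeSurfer-derived
#' measures: 7 subcortical gray-matter volumes, the mean lateral-ventricle
#' volume, 34 Desikan/Killiany cortical thickness and 34 surface-area
#' measures, and total intracranial volume (ICV). The registry fixes the
#' canonical column order and maps every averaged feature to its left/right
#' raw columns (ICV is unpaired).
#'
#' @return A data.frame with one row per averaged feature and columns
#'   `feature` (averaged column name), `modality` (one of
#'   `"subcortical_volume"`, `"ventricle"`, `"thickness"`,
#'   `"surface_area"`, `"icv"`), `region`, `left` and `right` (raw column
#'   names, `NA` for ICV).
#' @export
#' @examples
#' reg <- feature_registry()
#' nrow(reg)            # 77
#' table(reg$modality)
feature_registry <- function() {
  cort <- dk_regions()
  subc <- c("accumbens", "amygdala", "caudate", "hippocampus",
            "pallidum", "putamen", "thalamus")
  rows <- list(
    data.frame(region = subc, suffix = "vol",
               modality = "subcortical_volume", stringsAsFactors = FALSE),
    data.frame(region = "lateralventricle", suffix = "vol",
               modality = "ventricle", stringsAsFactors = FALSE),
    data.frame(region = cort, suffix = "thickavg",
               modality = "thickness", stringsAsFactors = FALSE),
    data.frame(region = cort, suffix = "surfarea",
               modality = "surface_area", stringsAsFactors = FALSE)
  )
  reg <- do.call(rbind, rows)
  reg$feature <- paste0("M_", reg$region, "_", reg$suffix)
  reg$left <- paste0("L_", reg$region, "_", reg$suffix)
  reg$right <- paste0("R_", reg$region, "_", reg$suffix)
  icv <- data.frame(region = "icv", suffix = "vol", modality = "icv",
                    feature = "ICV", left = NA_character_,
                    right = NA_character_, stringsAsFactors = FALSE)
  reg <- rbind(reg, icv)
  rownames(reg) <- NULL
  reg[, c("feature", "modality", "region", "suffix", "left", "right")]
}

# The 34 Desikan/Killiany cortical parcels.
dk_regions <- function() {
  c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal",
    "temporalpole", "transversetemporal")
}

#' Default per-feature simulation archetypes
#'
#' One row per averaged feature giving the mean function used by the
#' synthetic cohort generator: baseline `mu` at age 40 (native units:
#' mm3 for volumes, mm for thickness, mm2 for areas), linear age slope
#' `slope` per year, quadratic age term `quad` per year squared, additive
#' male offset `sex_off`, ICV coupling `icv_gamma` (dimensionless, 0 for
#' thickness), between-site offset SD `site_tau`, and residual SD `sigma`.
#'
#' Signs encode the canonical aging pattern: cortical thinning everywhere
#' except the entorhinal and temporal-pole parcels, ventricular expansion
#' (accelerating with age), shallow surface-area and subcortical decline,
#' and no age trend for ICV. Thickness features carry the largest
#' standardized age slopes of any modality, so a model trained on these
#' archetypes leans on thickness the way the aging literature suggests.
#'
#' @return A data.frame keyed by `feature`, aligned with
#'   [feature_registry()].
#' @export
feature_archetypes <- function() {
  reg <- feature_registry()
  cort <- dk_regions()

  th_mu <- c(bankssts = 2.45, caudalanteriorcingulate = 2.65,
             caudalmiddlefrontal = 2.58, cuneus = 1.90, entorhinal = 3.40,
             frontalpole = 2.75, fusiform = 2.72, inferiorparietal = 2.48,
             inferiortemporal = 2.75, insula = 3.05, isthmuscingulate = 2.45,
             lateraloccipital = 2.15, lateralorbitofrontal = 2.68,
             lingual = 2.00, medialorbitofrontal = 2.50,
             middletemporal = 2.80, paracentral = 2.42,
             parahippocampal = 2.75, parsopercularis = 2.60,
             parsorbitalis = 2.70, parstriangularis = 2.52,
             pericalcarine = 1.60, postcentral = 2.05,
             posteriorcingulate = 2.48, precentral = 2.55, precuneus = 2.35,
             rostralanteriorcingulate = 2.80, rostralmiddlefrontal = 2.40,
             superiorfrontal = 2.70, superiorparietal = 2.18,
             superiortemporal = 2.80, supramarginal = 2.55,
             temporalpole = 3.70, transversetemporal = 2.35)
  sa_mu <- c(bankssts = 990, caudalanteriorcingulate = 640,
             caudalmiddlefrontal = 2250, cuneus = 1450, entorhinal = 430,
             frontalpole = 270, fusiform = 3300, inferiorparietal = 4800,
             inferiortemporal = 3400, insula = 2250, isthmuscingulate = 970,
             lateraloccipital = 4900, lateralorbitofrontal = 2600,
             lingual = 3000, medialorbitofrontal = 1850,
             middletemporal = 3400, paracentral = 1500,
             parahippocampal = 720, parsopercularis = 1600,
             parsorbitalis = 680, parstriangularis = 1450,
             pericalcarine = 1400, postcentral = 4000,
             posteriorcingulate = 1200, precentral = 4800, precuneus = 3700,
             rostralanteriorcingulate = 800, rostralmiddlefrontal = 5800,
             superiorfrontal = 7000, superiorparietal = 5200,
             superiortemporal = 3800, supramarginal = 3600,
             temporalpole = 450, transversetemporal = 400)
  sc_mu <- c(accumbens = 550, amygdala = 1550, caudate = 3600,
             hippocampus = 4100, pallidum = 1750, putamen = 5000,
             thalamus = 7200)

  # deterministic regional heterogeneity in thinning rates
  th_rate <- rep(c(1.25, 0.80, 1.10, 0.90, 1.20, 0.70, 1.00), length.out = 34)
  names(th_rate) <- cort

  arch <- reg
  n <- nrow(arch)
  arch$mu <- numeric(n); arch$slope <- numeric(n); arch$quad <- numeric(n)
  arch$sex_off <- numeric(n); arch$icv_gamma <- numeric(n)
  arch$site_tau <- numeric(n); arch$sigma <- numeric(n)

  for (i in seq_len(n)) {
    m <- arch$modality[i]; rgn <- arch$region[i]
    if (m == "thickness") {
      mu <- th_mu[[rgn]]
      sl <- -0.0045 * th_rate[[rgn]]
      if (rgn %in% c("entorhinal", "temporalpole")) sl <- +0.0012
      arch$mu[i] <- mu
      arch$slope[i] <- sl
      arch$quad[i] <- if (rgn %in% c("entorhinal", "temporalpole")) 0 else -1.2e-5
      arch$sex_off[i] <- 0.01
      arch$icv_gamma[i] <- 0
      arch$sigma[i] <- 0.11
      arch$site_tau[i] <- 0.033
    } else if (m == "surface_area") {
      mu <- sa_mu[[rgn]]
      arch$mu[i] <- mu
      arch$slope[i] <- -0.0011 * mu
      arch$quad[i] <- 0
      arch$sex_off[i] <- 0.10 * mu
      arch$icv_gamma[i] <- 0.50 * mu / 1.5e6
      arch$sigma[i] <- 0.085 * mu
      arch$site_tau[i] <- 0.025 * mu
    } else if (m == "subcortical_volume") {
      mu <- sc_mu[[rgn]]
      arch$mu[i] <- mu
      rate <- if (rgn == "accumbens") -0.0038 else -0.0022
      arch$slope[i] <- rate * mu
      arch$quad[i] <- -2.0e-5 * mu
      arch$sex_off[i] <- 0.10 * mu
      arch$icv_gamma[i] <- 0.35 * mu / 1.5e6
      arch$sigma[i] <- 0.085 * mu
      arch$site_tau[i] <- 0.025 * mu
    } else if (m == "ventricle") {
      arch$mu[i] <- 7500
      arch$slope[i] <- 105
      arch$quad[i] <- 1.8
      arch$sex_off[i] <- 900
      arch$icv_gamma[i] <- 0.35 * 7500 / 1.5e6
      arch$sigma[i] <- 2800
      arch$site_tau[i] <- 700
    } else { # icv
      arch$mu[i] <- 1.45e6
      arch$slope[i] <- 0
      arch$quad[i] <- 0
      arch$sex_off[i] <- 1.7e5
      arch$icv_gamma[i] <- 1   # the ICV feature is the ICV covariate itself
      arch$sigma[i] <- 0       # measurement noise negligible at this scale
      arch$site_tau[i] <- 2.5e4
    }
  }
  arch
}
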