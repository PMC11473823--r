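#' Spectral class template for the synthetic REIMS generator
#'
#' A template lists the characteristic peaks of one tissue/material class
#' as (m/z, mean intensity, coefficient of variation) triples, plus the
#' mean intensity of additive low-level "chemical noise" peaks and of the
#' continuously infused leucine-enkephalin lockmass ion. Intensities are
#' in arbitrary detector counts; the shipped defaults are scaled so a
#' typical scan has a total ion count near 1e6.
#'
#' @param name One of `"normal_adipose"`, `"tumor"`, `"pork_liver"`,
#'   `"nist_homogenate"` (or any other label for custom templates).
#' @param peaks data.frame with columns `mz` (Da, unique), `mean_intensity`
#'   (>= 0), `cv` (lognormal coefficient of variation, >= 0) and optional
#'   logical `tg` marking triglyceride peaks subject to the
#'   coagulation-mode attenuation.
#' @param baseline_noise_level Mean intensity of a single chemical-noise
#'   peak; 0 disables the noise floor.
#' @param noise_peak_rate Expected number of noise peaks per scan.
#' @param lockmass_intensity Mean intensity of the LeuEnk lockmass peak.
#' @return An object of class `class_template`.
#' @export
class_template <- function(name, peaks, baseline_noise_level = 60,
                           noise_peak_rate = 300,
                           lockmass_intensity = 5e4) {
  stopifnot(is.data.frame(peaks), all(c("mz", "mean_intensity") %in%
                                        names(peaks)))
  if (is.null(peaks$cv)) peaks$cv <- 0.25
  if (is.null(peaks$tg)) peaks$tg <- FALSE
  if (anyDuplicated(peaks$mz)) stop("template peaks must be unique by m/z")
  if (any(peaks$mean_intensity < 0) || any(peaks$cv < 0)) {
    stop("mean_intensity and cv must be non-negative")
  }
  structure(list(name = name,
                 peaks = peaks[order(peaks$mz),
                               c("mz", "mean_intensity", "cv", "tg")],
                 baseline_noise_level = baseline_noise_level,
                 noise_peak_rate = noise_peak_rate,
                 lockmass_intensity = lockmass_intensity),
            class = "class_template")
}

# Theoretical m/z of the species placed in the default templates
.species_mz <- c(
  "FA(18:2)" = 279.2329, "FA(18:1)" = 281.2486, "FA(20:4)" = 303.2329,
  "FA(20:3)" = 305.2486, "FA(20:2)" = 307.2643, "FA(22:5)" = 329.2486,
  "FA(22:4)" = 331.2643, "DG(18:1/16:0)" = 629.4917, "PA(36:2)" = 699.4990,
  "PE(18:1/18:0)" = 744.5549, "PI(38:4)" = 885.5499, "TG(50:2)" = 865.7057,
  "TG(52:2)" = 893.7370, "TG(54:3)" = 919.7527, "TG(58:10)" = 925.7291)

.fa_channel_mz <- .species_mz[c("FA(18:2)", "FA(20:2)", "FA(20:3)",
                                "FA(20:4)", "FA(22:4)", "FA(22:5)")]

template_peaks <- function(rel, scale = 2e5) {
  mz <- .species_mz[names(rel)]
  data.frame(mz = unname(mz), mean_intensity = unname(rel) * scale,
             cv = 0.25, tg = grepl("^TG", names(rel)), row.names = NULL)
}

#' Default tissue templates
#'
#' Normal breast adipose is dominated by triglyceride chloride adducts
#' (m/z 865.71, 893.74, 919.75) with abundant FA(18:1); invasive tumor
#' tissue by glycerophospholipids (m/z 699.50, 744.55, 885.55) with
#' elevated FA(18:2) and arachidonic acid. `divergence` interpolates the
#' tumor template between the normal one (0, classes exchangeable) and
#' the full planted contrast (1, the default study condition).
#'
#' @param divergence Tumor/normal template divergence in `[0, 1]`.
#' @return Named list of [class_template()] objects: `normal_adipose`,
#'   `tumor`, `stroma` (the benign tissue partial tumors blend into),
#'   `pork_liver`, `nist_homogenate`.
#' @export
default_templates <- function(divergence = 1) {
  stopifnot(divergence >= 0, divergence <= 1)
  normal_rel <- c("TG(50:2)" = 0.95, "TG(52:2)" = 1.00, "TG(54:3)" = 0.80,
                  "TG(58:10)" = 0.22, "DG(18:1/16:0)" = 0.30,
                  "PA(36:2)" = 0.05, "PE(18:1/18:0)" = 0.06,
                  "PI(38:4)" = 0.04, "FA(18:1)" = 0.35, "FA(18:2)" = 0.10,
                  "FA(20:4)" = 0.030, "FA(20:3)" = 0.025, "FA(20:2)" = 0.020,
                  "FA(22:5)" = 0.015, "FA(22:4)" = 0.015)
  tumor_rel <- c("TG(50:2)" = 0.06, "TG(52:2)" = 0.07, "TG(54:3)" = 0.05,
                 "TG(58:10)" = 0.02, "DG(18:1/16:0)" = 0.05,
                 "PA(36:2)" = 0.75, "PE(18:1/18:0)" = 1.00,
                 "PI(38:4)" = 0.60, "FA(18:1)" = 0.12, "FA(18:2)" = 0.30,
                 "FA(20:4)" = 0.20, "FA(20:3)" = 0.08, "FA(20:2)" = 0.05,
                 "FA(22:5)" = 0.05, "FA(22:4)" = 0.05)
  # benign non-adipose stroma: the tissue a partial tumor blends into.
  # Mixed sampling regions are tumor + fibrous stroma, not tumor + pure
  # adipose (100% adipose is its own class), so even low-percentage tumor
  # points remain phospholipid-leaning.
  stroma_rel <- c("TG(50:2)" = 0.18, "TG(52:2)" = 0.20, "TG(54:3)" = 0.15,
                  "TG(58:10)" = 0.04, "DG(18:1/16:0)" = 0.10,
                  "PA(36:2)" = 0.35, "PE(18:1/18:0)" = 0.55,
                  "PI(38:4)" = 0.30, "FA(18:1)" = 0.18, "FA(18:2)" = 0.22,
                  "FA(20:4)" = 0.12, "FA(20:3)" = 0.05, "FA(20:2)" = 0.035,
                  "FA(22:5)" = 0.035, "FA(22:4)" = 0.035)
  tumor_rel <- normal_rel + divergence * (tumor_rel - normal_rel)
  stroma_rel <- normal_rel + divergence * (stroma_rel - normal_rel)
  liver_rel <- c("TG(50:2)" = 0.40, "TG(52:2)" = 0.50, "TG(54:3)" = 0.35,
                 "DG(18:1/16:0)" = 0.20, "PA(36:2)" = 0.50,
                 "PE(18:1/18:0)" = 0.80, "PI(38:4)" = 0.50,
                 "FA(18:1)" = 0.25, "FA(18:2)" = 0.25, "FA(20:4)" = 0.15,
                 "FA(20:3)" = 0.05, "FA(20:2)" = 0.04, "FA(22:5)" = 0.05,
                 "FA(22:4)" = 0.04)
  nist_rel <- c("TG(50:2)" = 0.60, "TG(52:2)" = 0.70, "TG(54:3)" = 0.50,
                "DG(18:1/16:0)" = 0.25, "PA(36:2)" = 0.30,
                "PE(18:1/18:0)" = 0.50, "PI(38:4)" = 0.25,
                "FA(18:1)" = 0.30, "FA(18:2)" = 0.20, "FA(20:4)" = 0.10,
                "FA(20:3)" = 0.04, "FA(20:2)" = 0.03, "FA(22:5)" = 0.03,
                "FA(22:4)" = 0.03)
  list(normal_adipose = class_template("normal_adipose",
                                       template_peaks(normal_rel)),
       tumor = class_template("tumor", template_peaks(tumor_rel)),
       stroma = class_template("stroma", template_peaks(stroma_rel)),
       pork_liver = class_template("pork_liver", template_peaks(liver_rel)),
       nist_homogenate = class_template("nist_homogenate",
                                        template_peaks(nist_rel)))
}

#' Per-site acquisition effect
#'
#' Multi-centre REIMS signal differs strongly between sites; the generator
#' models this as a per-site overall intensity scale, a small constant mass
#' drift (undone by lockmass correction), a chemical-noise-floor scale, and
#' an attenuation of triglyceride peaks in coagulation mode.
#'
#' In addition to unstructured per-scan chemical noise, every site
#' carries a reproducible background: `n_background` low-abundance
#' contaminant ions at site-specific (but scan-invariant) m/z positions,
#' derived deterministically from `site_id`. These consistent
#' low-abundance peaks are what make spectra identifiable by site even
#' when the tissue signal is shared.
#'
#' @param site_id Site label, e.g. `"C1"`.
#' @param intensity_scale,noise_floor_scale Positive multipliers.
#' @param mass_drift Signed constant m/z offset, |drift| <= 0.05 Da.
#' @param coag_tg_shift Multiplier applied to TG peaks in coagulation mode.
#' @param n_background Number of consistent site background ions.
#' @param mass_response_slope Site instrument-response tilt: every peak is
#'   scaled by `exp(slope * (mz - 800) / 200)`, modelling mass-dependent
#'   transmission/tuning differences between instruments (0 = flat).
#' @return An object of class `site_effect`.
#' @export
site_effect <- function(site_id, intensity_scale = 1, mass_drift = 0,
                        noise_floor_scale = 1, coag_tg_shift = 1,
                        n_background = 40, mass_response_slope = 0) {
  stopifnot(intensity_scale > 0, noise_floor_scale > 0, coag_tg_shift > 0,
            abs(mass_drift) <= 0.05, n_background >= 0)
  structure(list(site_id = site_id, intensity_scale = intensity_scale,
                 mass_drift = mass_drift,
                 noise_floor_scale = noise_floor_scale,
                 coag_tg_shift = coag_tg_shift,
                 n_background = as.integer(n_background),
                 mass_response_slope = mass_response_slope),
            class = "site_effect")
}

# Scan-invariant background ion positions for a site, derived from the
# site id so they never depend on (or disturb) the simulation stream.
site_background_mz <- function(site) {
  n <- site$n_background %||% 0L
  if (n == 0L) return(numeric())
  h <- sum(utf8ToInt(site$site_id) * seq_along(utf8ToInt(site$site_id)))
  h <- (h * 2654435761) %% 2147483647
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(h))
  sort(stats::runif(n, 600, 1000))
}

#' Default three-site effect set
#'
#' Magnitudes are this generator's choices (the study reports strong
#' inter-site intensity differences but no numbers): a low-signal noisy
#' site, a reference site and a high-signal clean site.
#' @return List of three [site_effect()] objects (C1, C3, C4).
#' @export
default_sites <- function() {
  list(site_effect("C1", intensity_scale = 1.0, mass_drift = 0.010,
                   noise_floor_scale = 1.0, coag_tg_shift = 0.85,
                   mass_response_slope = 0),
       site_effect("C3", intensity_scale = 0.45, mass_drift = -0.015,
                   noise_floor_scale = 1.6, coag_tg_shift = 0.75,
                   mass_response_slope = -0.15),
       site_effect("C4", intensity_scale = 1.8, mass_drift = 0.020,
                   noise_floor_scale = 0.7, coag_tg_shift = 0.90,
                   mass_response_slope = 0.15))
}

#' Default PIK3CA-mutant fatty-acid effect multipliers
#'
#' Mutant tumors show decreased FA(18:2) and increased FA(20:2), FA(20:3),
#' FA(22:4) and FA(22:5) channels (arachidonic acid itself unchanged).
#' @return Named numeric vector over the six FA channels.
#' @export
default_fa_effects <- function() {
  c("FA(18:2)" = 0.60, "FA(20:2)" = 1.40, "FA(20:3)" = 1.50,
    "FA(20:4)" = 1.00, "FA(22:4)" = 1.60, "FA(22:5)" = 1.60)
}

#' Attenuate planted FA effect sizes
#'
#' Interpolates multiplicative effects toward the identity on the log
#' scale: `scale_fa_effects(e, 0)` is all-ones, `scale_fa_effects(e, 1)`
#' is `e`.
#' @param effects Named positive multipliers.
#' @param s Scale in `[0, 1]` (values > 1 extrapolate).
#' @return Scaled multipliers.
#' @export
scale_fa_effects <- function(effects, s) exp(s * log(effects))

#' Synthetic cohort design
#'
#' Describes the sites-by-patients-by-points-by-scans structure a
#' simulated multi-centre study follows, the cut/coagulation mode mix, the
#' fraction of tumor sampling points, how tumor-cell percentages are drawn
#' (a point-blank mixture placing some mass below the 30% labeling
#' threshold so the exclusion rule is exercised), and the PIK3CA-mutant
#' fatty-acid effects.
#'
#' `preset = "table1_like"` reproduces the published cohort shape: 3 sites
#' x 7 patients x 10 sampling points, one scan each, with exactly 82/57
#' normal cut/coagulation and 39/32 tumor cut/coagulation points and all
#' tumor points at >= 30% tumor cells.
#'
#' @param sites List of [site_effect()]; default [default_sites()].
#' @param patients_per_site,points_per_patient,scans_per_point Counts >= 1.
#' @param mode_mix Fraction of points acquired in cut mode.
#' @param tumor_fraction Fraction of tumor sampling points.
#' @param tumor_pct_sampler Function `n -> n` tumor-cell percentages in
#'   (0, 100]; the default draws 80% from U(30, 95) and 20% from U(1, 29).
#' @param patient_cv,point_cv Biological variability: lognormal
#'   coefficient of variation of per-peak template intensities at the
#'   patient and sampling-point level (defaults 0.35 and 0.20). These
#'   correlated, hierarchical perturbations are what give within-class
#'   spread beyond shot-to-shot noise, so leave-patient-out folds face
#'   genuinely new patients.
#' @param noise_jitter_cv,slope_jitter_sd Within-site acquisition drift:
#'   per sampling point the site's noise floor is scaled by a lognormal
#'   factor (cv 0.5) and its instrument-response slope jittered by a
#'   normal deviate (sd 0.08), so site-level differences are shifts of
#'   distributions that already vary within a site rather than fixed
#'   offsets no training fold has seen.
#' @param pik3ca_mut_fraction Fraction of tumor-bearing patients with a
#'   PIK3CA mutation.
#' @param fa_effect_sizes Named multipliers over the six FA channels
#'   applied to the tumor template of mutant patients.
#' @param templates Named list with `normal_adipose` and `tumor`
#'   [class_template()]s; default [default_templates()].
#' @param triple_neg_fraction Fraction of patients with triple-negative
#'   hormone-receptor status.
#' @param seed Integer seed; all sub-streams derive from it.
#' @param preset `NULL` or `"table1_like"`.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(sites = default_sites(), patients_per_site = 6,
                          points_per_patient = 6, scans_per_point = 2,
                          mode_mix = 0.6, tumor_fraction = 0.4,
                          tumor_pct_sampler = NULL,
                          pik3ca_mut_fraction = 0.66,
                          fa_effect_sizes = default_fa_effects(),
                          templates = default_templates(),
                          triple_neg_fraction = 0.3,
                          patient_cv = 0.35, point_cv = 0.20,
                          noise_jitter_cv = 0.5, slope_jitter_sd = 0.08,
                          seed = 1L, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "table1_like")
    patients_per_site <- 7L
    points_per_patient <- 10L
    scans_per_point <- 1L
    tumor_pct_sampler <- function(n) stats::runif(n, 30, 95)
  }
  if (length(sites) < 1L) stop("cohort config error: at least one site")
  stopifnot(patients_per_site >= 1, points_per_patient >= 1,
            scans_per_point >= 1, mode_mix >= 0, mode_mix <= 1,
            tumor_fraction >= 0, tumor_fraction <= 1,
            pik3ca_mut_fraction >= 0, pik3ca_mut_fraction <= 1)
  if (is.null(tumor_pct_sampler)) {
    tumor_pct_sampler <- function(n) {
      ifelse(stats::runif(n) < 0.8, stats::runif(n, 30, 95),
             stats::runif(n, 1, 29))
    }
  }
  structure(list(sites = sites, patients_per_site = patients_per_site,
                 points_per_patient = points_per_patient,
                 scans_per_point = scans_per_point, mode_mix = mode_mix,
                 tumor_fraction = tumor_fraction,
                 tumor_pct_sampler = tumor_pct_sampler,
                 pik3ca_mut_fraction = pik3ca_mut_fraction,
                 fa_effect_sizes = fa_effect_sizes, templates = templates,
                 triple_neg_fraction = triple_neg_fraction,
                 patient_cv = patient_cv, point_cv = point_cv,
                 noise_jitter_cv = noise_jitter_cv,
                 slope_jitter_sd = slope_jitter_sd,
                 seed = as.integer(seed), preset = preset),
            class = "cohort_config")
}

#' Simulate one REIMS scan
#'
#' Places the template peaks (shifted by the site's mass drift) with
#' lognormal intensity noise at the given coefficient of variation,
#' mean-corrected so the expected intensity equals the template mean;
#' adds the LeuEnk lockmass peak near m/z 554.26, the site's consistent
#' background ions, and a Poisson-distributed number of exponential
#' low-level chemical-noise peaks at random positions. In coagulation
#' mode the site's TG attenuation applies. Uses R's global RNG: the same
#' seed gives an identical scan.
#'
#' @param template A [class_template()].
#' @param site A [site_effect()] or `NULL` for a neutral site.
#' @param mode `"cut"` or `"coag"`.
#' @param scan_id Scan identifier.
#' @return A [reims_spectrum()]. A template with all-zero intensities and
#'   no noise yields an empty spectrum flagged `attr(, "pure_noise")`.
#' @export
simulate_spectrum <- function(template, site = NULL, mode = c("cut", "coag"),
                              scan_id = "scan1") {
  stopifnot(inherits(template, "class_template"))
  mode <- match.arg(mode)
  if (is.null(site)) site <- site_effect("S0")
  pk <- template$peaks
  means <- pk$mean_intensity * site$intensity_scale
  if (mode == "coag") means[pk$tg] <- means[pk$tg] * site$coag_tg_shift
  sigma <- sqrt(log1p(pk$cv^2))
  ints <- means * exp(stats::rnorm(nrow(pk), 0, sigma) - sigma^2 / 2)
  mz <- pk$mz

  # lockmass ion, always present; varies with the template's typical cv
  cv_lock <- if (nrow(pk)) mean(pk$cv) else 0
  sl <- sqrt(log1p(cv_lock^2))
  lock_int <- template$lockmass_intensity * site$intensity_scale *
    exp(stats::rnorm(1, 0, sl) - sl^2 / 2)
  mz <- c(mz, 554.2615)
  ints <- c(ints, lock_int)

  # consistent site background ions (fixed m/z per site, intensity varies)
  bg_mz <- site_background_mz(site)
  if (length(bg_mz) && template$baseline_noise_level > 0) {
    bg_mean <- 10 * template$baseline_noise_level * site$noise_floor_scale
    sb <- sqrt(log1p(0.4^2))
    mz <- c(mz, bg_mz)
    ints <- c(ints, bg_mean * exp(stats::rnorm(length(bg_mz), 0, sb) -
                                    sb^2 / 2))
  }

  if (template$baseline_noise_level > 0 && template$noise_peak_rate > 0) {
    n_noise <- stats::rpois(1, template$noise_peak_rate *
                              site$noise_floor_scale)
    if (n_noise > 0) {
      mz <- c(mz, stats::runif(n_noise, 150, 1000))
      ints <- c(ints, stats::rexp(n_noise, 1 / (template$baseline_noise_level *
                                                  site$noise_floor_scale)))
    }
  }
  slope <- site$mass_response_slope %||% 0
  if (slope != 0) ints <- ints * exp(slope * (mz - 800) / 200)
  mz <- mz + site$mass_drift
  o <- order(mz)
  mz <- mz[o]; ints <- ints[o]
  if (anyDuplicated(mz)) {                 # merge exact m/z collisions
    ints <- as.numeric(tapply(ints, factor(mz, levels = unique(mz)), sum))
    mz <- unique(mz)
  }
  keep <- ints > 0
  s <- reims_spectrum(scan_id, mz[keep], ints[keep])
  if (all(pk$mean_intensity == 0)) attr(s, "pure_noise") <- TRUE
  s
}

blend_templates <- function(normal, tumor, w) {
  mzs <- sort(union(normal$peaks$mz, tumor$peaks$mz))
  get <- function(tpl, col, default) {
    v <- rep(default, length(mzs))
    i <- match(tpl$peaks$mz, mzs)
    v[i] <- tpl$peaks[[col]]
    v
  }
  mn <- (1 - w) * get(normal, "mean_intensity", 0) +
    w * get(tumor, "mean_intensity", 0)
  cv <- pmax(get(normal, "cv", 0.25), get(tumor, "cv", 0.25))
  tg <- get(normal, "tg", FALSE) | get(tumor, "tg", FALSE)
  class_template(sprintf("blend_%.2f", w),
                 data.frame(mz = mzs, mean_intensity = mn, cv = cv, tg = tg),
                 baseline_noise_level = (1 - w) * normal$baseline_noise_level +
                   w * tumor$baseline_noise_level,
                 noise_peak_rate = (1 - w) * normal$noise_peak_rate +
                   w * tumor$noise_peak_rate,
                 lockmass_intensity = (1 - w) * normal$lockmass_intensity +
                   w * tumor$lockmass_intensity)
}

# Correlated biological perturbation: one lognormal multiplier per
# template peak, mean-corrected so expected intensities are unchanged.
perturb_template <- function(template, cv) {
  if (is.null(cv) || cv <= 0) return(template)
  sig <- sqrt(log1p(cv^2))
  f <- exp(stats::rnorm(nrow(template$peaks), 0, sig) - sig^2 / 2)
  template$peaks$mean_intensity <- template$peaks$mean_intensity * f
  template
}

apply_fa_effects <- function(template, effects) {
  pk <- template$peaks
  i <- match(round(.fa_channel_mz[names(effects)], 4), round(pk$mz, 4))
  ok <- !is.na(i)
  pk$mean_intensity[i[ok]] <- pk$mean_intensity[i[ok]] * effects[ok]
  template$peaks <- pk
  template
}

#' Simulate a multi-site REIMS cohort
#'
#' Draws the full hierarchy described by a [cohort_config()]: per-site
#' patients, per-patient sampling points (each a tumor or normal "burn"
#' with a cautery mode), and per-point 1-second scans. Tumor points blend
#' the tumor and benign-stroma templates by the drawn tumor-cell
#' percentage, so low-percentage points look intermediate between tumor
#' and stroma (not between tumor and pure adipose, which is its own
#' class); PIK3CA-mutant
#' patients get the configured FA channel effects applied to their tumor
#' template component. Tissue labels are left `"unassigned"`;
#' [assign_labels()] derives them from the recorded tumor-cell
#' percentages downstream.
#'
#' @param config A [cohort_config()].
#' @return List with elements `dataset` (a [reims_dataset()]) and `truth`
#'   (one row per scan: true class, site, patient, point, mode,
#'   tumor-cell percentage, PIK3CA status, planted FA multipliers).
#' @examples
#' cfg <- cohort_config(patients_per_site = 2, points_per_patient = 2,
#'                      scans_per_point = 1, seed = 7)
#' sim <- simulate_cohort(cfg)
#' sim$dataset
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(config$sites) == 0L) stop("cohort config error: zero sites")
  set.seed(config$seed)
  tpl_n <- config$templates$normal_adipose
  tpl_t <- config$templates$tumor
  tpl_s <- config$templates$stroma %||% tpl_n
  n_sites <- length(config$sites)
  npat <- config$patients_per_site
  nppp <- config$points_per_patient
  nspp <- config$scans_per_point

  preset_alloc <- NULL
  if (identical(config$preset, "table1_like")) {
    tuples <- rbind(
      data.frame(class = "normal", mode = "cut")[rep(1, 82), ],
      data.frame(class = "normal", mode = "coag")[rep(1, 57), ],
      data.frame(class = "tumor", mode = "cut")[rep(1, 39), ],
      data.frame(class = "tumor", mode = "coag")[rep(1, 32), ])
    preset_alloc <- tuples[sample.int(nrow(tuples)), ]
  }

  spectra <- list(); meta_rows <- list(); truth_rows <- list()
  point_counter <- 0L
  for (si in seq_len(n_sites)) {
    site <- config$sites[[si]]
    analyst <- paste0("A", si)
    for (pj in seq_len(npat)) {
      patient <- sprintf("%s_P%02d", site$site_id, pj)
      mut <- stats::runif(1) < config$pik3ca_mut_fraction
      pik3ca <- if (mut) "Mut" else "WT"
      hr <- if (stats::runif(1) < config$triple_neg_fraction)
        "triple_neg" else "ERPR_pos"
      tpl_t_pat <- if (mut)
        apply_fa_effects(tpl_t, config$fa_effect_sizes) else tpl_t
      # patient-level biology: correlated template perturbations
      tpl_n_pat <- perturb_template(tpl_n, config$patient_cv)
      tpl_s_pat <- perturb_template(tpl_s, config$patient_cv)
      tpl_t_pat <- perturb_template(tpl_t_pat, config$patient_cv)
      for (pp in seq_len(nppp)) {
        point_counter <- point_counter + 1L
        point <- sprintf("pt%03d", point_counter)
        if (!is.null(preset_alloc)) {
          is_tumor <- preset_alloc$class[point_counter] == "tumor"
          mode <- preset_alloc$mode[point_counter]
        } else {
          is_tumor <- stats::runif(1) < config$tumor_fraction
          mode <- if (stats::runif(1) < config$mode_mix) "cut" else "coag"
        }
        if (is_tumor) {
          pct <- config$tumor_pct_sampler(1)
          # partial tumor blends into benign stroma, not into pure adipose
          tpl <- blend_templates(tpl_s_pat, tpl_t_pat, pct / 100)
          pure <- FALSE
        } else {
          pct <- 0
          tpl <- tpl_n_pat
          pure <- TRUE
        }
        tpl <- perturb_template(tpl, config$point_cv)
        # per-point acquisition drift around the site's nominal settings
        site_pt <- site
        if (config$noise_jitter_cv > 0) {
          sj <- sqrt(log1p(config$noise_jitter_cv^2))
          site_pt$noise_floor_scale <- site$noise_floor_scale *
            exp(stats::rnorm(1, 0, sj) - sj^2 / 2)
        }
        if (config$slope_jitter_sd > 0) {
          site_pt$mass_response_slope <- site$mass_response_slope +
            stats::rnorm(1, 0, config$slope_jitter_sd)
        }
        for (sc in seq_len(nspp)) {
          scan_id <- sprintf("%s_%s_s%d", patient, point, sc)
          spectra[[scan_id]] <-
            simulate_spectrum(tpl, site_pt, mode, scan_id = scan_id)
          meta_rows[[scan_id]] <- scan_metadata(
            scan_id, site_id = site$site_id, patient_id = patient,
            point_id = point, analyst_id = analyst, cautery_mode = mode,
            tissue_label = "unassigned", tumor_cell_pct = pct,
            adipose_pure = pure,
            pik3ca_status = if (is_tumor) pik3ca else "unknown",
            hr_status = hr)
          truth_rows[[scan_id]] <- data.frame(
            scan_id = scan_id,
            true_class = if (is_tumor) "tumor" else "normal",
            site_id = site$site_id, patient_id = patient, point_id = point,
            cautery_mode = mode, tumor_cell_pct = pct,
            pik3ca_status = if (is_tumor) pik3ca else "unknown",
            hr_status = hr,
            fa_effect_applied = is_tumor && mut,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  dataset <- reims_dataset(unname(spectra), do.call(rbind, meta_rows),
                           provenance = sprintf(
                             "simulate_cohort(seed=%d): %d sites x %d patients x %d points x %d scans",
                             config$seed, n_sites, npat, nppp, nspp))
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(dataset = dataset, truth = truth)
}
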