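#' Configuration of a synthetic two-class spectral cohort
#'
#' Describes a cohort whose bin pairs follow class-specific linear relations
#' with Gaussian residuals — the statistical structure the dual pairwise
#' models assume. The disease pattern is concentrated on a few *hub* bins:
#' each hub drives a block of partner bins through a linear coupling whose
#' slope/intercept differ between the classes, so patient networks become
#' star-like around the hubs while control networks stay unstructured.
#'
#' Defaults emulate an NMR-style study: 200 bins, 25 control and 25 disease
#' subjects, 3 hubs with 30 partners each, and class couplings that differ
#' only by a slope offset of 1.0: control
#' `partner = 1.0 * hub + N(0, 0.1^2)` versus disease
#' `partner = 2.0 * hub + N(0, 0.1^2)`. At a baseline level of 10 the two
#' regression lines are therefore far apart over the whole hub range, so
#' pattern pairs are decisively disease-like for patients and control-like
#' for controls — the regime in which the star-like patient networks of the
#' method's motivating studies arise. Non-pattern bins are independent
#' `baseline_level + N(0, background_noise_std^2)` in both classes.
#'
#' @param n_bins Number of spectral bins (nodes).
#' @param m_control,m_disease Subjects per class (each at least 3).
#' @param hub_bins Either the number of hubs (scalar) or explicit hub bin
#'   indices. By default hubs sit at evenly spaced positions.
#' @param partners_per_hub Partner bins per hub, taken as the run of bins
#'   immediately after each hub.
#' @param control_coupling,disease_coupling Named numeric vectors
#'   `c(slope, intercept, resid_std)` of the pattern-pair law in each class.
#' @param background_noise_std Standard deviation of non-pattern bins and of
#'   the hub bins themselves.
#' @param baseline_level Mean intensity of hub and non-pattern bins.
#' @param disease_strength In `[0, 1]`: 0 makes the two class generators
#'   identical (null cohort); 1 applies the full disease coupling;
#'   intermediate values interpolate slope/intercept/residual linearly.
#' @param seed Integer seed; all randomness flows from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_bins = 200, m_control = 25, m_disease = 25,
                          hub_bins = 3, partners_per_hub = 30,
                          control_coupling = c(slope = 1.0, intercept = 0.0,
                                               resid_std = 0.1),
                          disease_coupling = c(slope = 2.0, intercept = 0.0,
                                               resid_std = 0.1),
                          background_noise_std = 1.0, baseline_level = 10.0,
                          disease_strength = 1.0, seed = 42L) {
  if (length(hub_bins) == 1 && hub_bins <= n_bins / (partners_per_hub + 2)) {
    # scalar: interpreted as the number of hubs, placed evenly
    k <- as.integer(hub_bins)
    hub_bins <- round(n_bins * seq_len(k) / (k + 1))
  }
  hub_bins <- as.integer(hub_bins)
  cfg <- structure(
    list(n_bins = as.integer(n_bins), m_control = as.integer(m_control),
         m_disease = as.integer(m_disease), hub_bins = hub_bins,
         partners_per_hub = as.integer(partners_per_hub),
         control_coupling = coupling_vec(control_coupling),
         disease_coupling = coupling_vec(disease_coupling),
         background_noise_std = background_noise_std,
         baseline_level = baseline_level,
         disease_strength = disease_strength, seed = as.integer(seed)),
    class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

coupling_vec <- function(x) {
  x <- as.numeric(x)
  if (length(x) != 3) stop("a coupling is c(slope, intercept, resid_std)",
                           call. = FALSE)
  stats::setNames(x, c("slope", "intercept", "resid_std"))
}

validate_cohort_config <- function(cfg) {
  problems <- character()
  p <- function(msg) problems <<- c(problems, msg)
  if (cfg$n_bins < 2) p("n_bins must be at least 2")
  if (cfg$m_control < 3 || cfg$m_disease < 3) p("each class needs >= 3 subjects")
  if (anyDuplicated(cfg$hub_bins)) p("hub bins must be distinct")
  if (any(cfg$hub_bins < 1 | cfg$hub_bins > cfg$n_bins)) p("hub bins out of range")
  if (cfg$partners_per_hub < 1) p("partners_per_hub must be positive")
  prt <- partner_map(cfg)
  if (any(unlist(prt) > cfg$n_bins)) p("partner blocks exceed n_bins")
  if (any(unlist(prt) %in% cfg$hub_bins)) p("partner blocks overlap a hub")
  if (anyDuplicated(unlist(prt))) p("partner blocks overlap each other")
  if (cfg$control_coupling["resid_std"] <= 0 ||
      cfg$disease_coupling["resid_std"] <= 0) p("residual stds must be > 0")
  if (cfg$background_noise_std <= 0) p("background_noise_std must be > 0")
  if (cfg$disease_strength < 0 || cfg$disease_strength > 1)
    p("disease_strength must be in [0, 1]")
  if (length(problems) > 0) {
    stop("invalid cohort configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  invisible(cfg)
}

# partner bins of each hub: the partners_per_hub indices right after the hub
partner_map <- function(cfg) {
  lapply(cfg$hub_bins, function(h) h + seq_len(cfg$partners_per_hub))
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config: %d bins, %d control + %d disease, seed %d>\n",
              x$n_bins, x$m_control, x$m_disease, x$seed))
  cat(sprintf("  hubs at %s, %d partners each; disease_strength %g\n",
              paste(x$hub_bins, collapse = ", "), x$partners_per_hub,
              x$disease_strength))
  invisible(x)
}

#' Generate a synthetic two-class cohort
#'
#' Draws a [spectral_dataset()] according to a [cohort_config()]: hub and
#' non-pattern bins are `baseline_level + N(0, background_noise_std^2)`
#' independently in both classes; each partner bin follows
#' `slope * hub + intercept + N(0, resid_std^2)` with the class-specific
#' coupling (for disease subjects, interpolated toward the control coupling
#' by `disease_strength`). Deterministic given `config$seed` (or the `seed`
#' override).
#'
#' @param config A [cohort_config()].
#' @param seed Optional override of `config$seed`.
#' @return A [spectral_dataset()] with `m_control + m_disease` rows, bin
#'   axis `1:n_bins`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_bins = 20, seed = 1))
#' cohort
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  validate_cohort_config(config)
  if (is.null(seed)) seed <- config$seed
  withr::with_seed(as.integer(seed), {
    xc <- draw_class(config, config$control_coupling, config$m_control)
    xd <- draw_class(config, disease_coupling_at(config, config$disease_strength),
                     config$m_disease)
  })
  ids <- c(sprintf("control_%03d", seq_len(config$m_control)),
           sprintf("disease_%03d", seq_len(config$m_disease)))
  labels <- rep(c("control", "disease"), c(config$m_control, config$m_disease))
  out <- spectral_dataset(rbind(xc, xd), ids, labels,
                          bin_axis = seq_len(config$n_bins), bin_width = 1)
  add_provenance(out, sprintf(
    "synthetic cohort: %d bins, %d+%d subjects, hubs [%s] x %d partners, strength %g, seed %d",
    config$n_bins, config$m_control, config$m_disease,
    paste(config$hub_bins, collapse = ","), config$partners_per_hub,
    config$disease_strength, as.integer(seed)))
}

# linear interpolation of the coupling: strength 0 -> control law (null),
# strength 1 -> full disease law
disease_coupling_at <- function(cfg, strength) {
  (1 - strength) * cfg$control_coupling + strength * cfg$disease_coupling
}

draw_class <- function(cfg, coupling, m) {
  n <- cfg$n_bins
  x <- matrix(stats::rnorm(m * n, cfg$baseline_level, cfg$background_noise_std),
              m, n)
  partners <- partner_map(cfg)
  for (k in seq_along(cfg$hub_bins)) {
    h <- x[, cfg$hub_bins[k]]
    for (pbin in partners[[k]]) {
      x[, pbin] <- coupling["slope"] * h + coupling["intercept"] +
        stats::rnorm(m, 0, coupling["resid_std"])
    }
  }
  x
}

#' Generate a longitudinal series of synthetic subjects
#'
#' One subject per timepoint, each drawn from the cohort generator's disease
#' model at the corresponding `disease_strength` — emulating a patient whose
#' disease signal waxes and wanes under treatment, for link-density
#' tracking with [track_evolution()].
#'
#' @param config A [cohort_config()] (its own `disease_strength` is ignored).
#' @param strengths Numeric vector in `[0, 1]`, one per timepoint.
#' @param seed Integer seed.
#' @return A tibble with columns `timepoint`, `disease_strength`, and a
#'   `values` list column of bin-intensity vectors.
#' @export
generate_trajectory <- function(config = cohort_config(), strengths, seed = 1L) {
  validate_cohort_config(config)
  if (length(strengths) == 0) stop("strengths must be non-empty", call. = FALSE)
  if (any(strengths < 0 | strengths > 1)) {
    stop("strengths must lie in [0, 1]", call. = FALSE)
  }
  values <- withr::with_seed(as.integer(seed), {
    lapply(strengths, function(s) {
      as.numeric(draw_class(config, disease_coupling_at(config, s), 1))
    })
  })
  tibble::tibble(timepoint = seq_along(strengths),
                 disease_strength = as.numeric(strengths),
                 values = values)
}
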