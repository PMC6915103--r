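# Intracochlear voltage-spread telemetry emulation.
#
# The implant's back-telemetry protocol records, for every stimulating
# contact, the voltage at every other contact at the plateau of the anodic
# pulse phase; in a purely resistive model that plateau equals the
# steady-state spread-matrix entry at the stimulus amplitude. Synthetic
# measurement cohorts add a per-subject lognormal scale (anatomy/impedance
# variability), per-entry multiplicative noise, and basally-weighted missing
# electrodes (deactivated contacts or outlying impedances).

#' Construct a measurement set
#'
#' @param values square matrix of measured voltages (V), `NA` where missing.
#' @param subject subject identifier.
#' @param amplitude_uA stimulation amplitude in microampere (> 0).
#' @param mask_reason character matrix matching `values`; reason for each
#'   `NA` entry (`"deactivated"` or `"outlier-impedance"`).
#' @return an object of class `measurement_set`.
#' @export
measurement_set <- function(values, subject = "S1", amplitude_uA = 50,
                            mask_reason = NULL) {
  values <- as.matrix(values)
  attributes(values) <- list(dim = dim(values))
  if (nrow(values) != ncol(values)) stop("spread matrix must be square")
  if (amplitude_uA <= 0) stop("amplitude must be > 0")
  if (is.null(mask_reason)) {
    mask_reason <- matrix(NA_character_, nrow(values), ncol(values))
    mask_reason[is.na(values)] <- "deactivated"
  }
  bad <- is.na(values) & is.na(mask_reason) & row(values) != col(values)
  if (any(bad)) stop("masked entries must carry a reason")
  structure(list(values = values, subject = subject,
                 amplitude_uA = amplitude_uA, mask_reason = mask_reason),
            class = "measurement_set")
}

#' Simulate a telemetry measurement cohort
#'
#' Each subject's matrix is the ground-truth spread matrix scaled by a
#' per-subject lognormal factor and per-entry multiplicative lognormal noise
#' (both with unit mean and coefficient of variation `noise_cv`), with
#' electrodes dropped preferentially at the basal end of the array.
#'
#' @param truth a `voltage_spread` matrix (or plain square matrix, V).
#' @param n_subjects cohort size (default 16 ears).
#' @param noise_cv coefficient of variation of the multiplicative noise;
#'   0 reproduces the truth exactly.
#' @param missing_policy list with `rate` (expected fraction of electrodes
#'   missing per subject), `basal_bias` (e-folding, in contacts, of the
#'   missingness weight from the basal end) and `p_outlier` (probability a
#'   missing electrode is flagged `outlier-impedance` rather than
#'   `deactivated`).
#' @param seed integer seed; the cohort is fully reproducible given it.
#' @param subject_cv CV of the per-subject scale; defaults to `noise_cv`.
#' @return list of [measurement_set()] objects.
#' @export
simulate_measurements <- function(truth, n_subjects = 16L, noise_cv = 0.3,
                                  missing_policy = list(rate = 0.1,
                                                        basal_bias = 2.5,
                                                        p_outlier = 0.3),
                                  seed = 1L, subject_cv = NULL) {
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  subject_cv <- subject_cv %||% noise_cv
  truth <- unclass(truth)
  nc <- ncol(truth)
  amplitude_uA <- (attr(truth, "amplitude_A") %||% 50e-6) * 1e6
  sdl <- function(cv) sqrt(log(1 + cv^2))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  rate <- missing_policy$rate %||% 0
  bias <- missing_policy$basal_bias %||% 2.5
  p_out <- missing_policy$p_outlier %||% 0.3
  wmiss <- exp(-(seq_len(nc) - 1L) / bias)
  pmiss <- pmin(1, rate * nc * wmiss / sum(wmiss))
  lapply(seq_len(n_subjects), function(k) {
    scale <- if (subject_cv > 0)
      stats::rlnorm(1L, -sdl(subject_cv)^2 / 2, sdl(subject_cv)) else 1
    noise <- if (noise_cv > 0)
      matrix(stats::rlnorm(nc * nc, -sdl(noise_cv)^2 / 2, sdl(noise_cv)), nc, nc)
      else 1
    vals <- truth * scale * noise
    reason <- matrix(NA_character_, nc, nc)
    drop <- which(stats::runif(nc) < pmiss)
    for (el in drop) {
      why <- if (stats::runif(1L) < p_out) "outlier-impedance" else "deactivated"
      vals[el, ] <- NA_real_
      vals[, el] <- NA_real_
      reason[el, ] <- why
      reason[, el] <- why
    }
    diag(vals) <- NA_real_
    diag(reason) <- NA_character_
    measurement_set(vals, subject = sprintf("SYN%02d", k),
                    amplitude_uA = amplitude_uA, mask_reason = reason)
  })
}

#' Compare a simulated spread matrix against a measurement cohort
#'
#' For one stimulating contact: across-subject mean and standard deviation
#' per measuring contact (stimulating-contact entries excluded, as a
#' resistive model carries no electrode-lymph interface), the fraction of
#' simulated values falling within mean +/- 1 SD, and the signed bias of the
#' simulation against the mean curve.
#'
#' @param sim simulated `voltage_spread` matrix (V).
#' @param meas list of [measurement_set()] objects.
#' @param stim_pair stimulating contact index.
#' @return an object of class `comparison_stats`.
#' @export
compare_to_measurements <- function(sim, meas, stim_pair) {
  sim <- unclass(sim)
  nc <- ncol(sim)
  rows <- matrix(NA_real_, length(meas), nc)
  skipped <- character(0)
  for (k in seq_along(meas)) {
    m <- meas[[k]]
    if (ncol(m$values) != nc) stop("mismatched contact counts")
    r <- m$values[stim_pair, ]
    if (all(is.na(r[-stim_pair]))) {
      skipped <- c(skipped, m$subject)
      next
    }
    rows[k, ] <- r
  }
  if (length(skipped))
    warning("subjects with no usable entries skipped: ",
            paste(skipped, collapse = ", "))
  rows <- rows[rowSums(!is.na(rows)) > 0L, , drop = FALSE]
  meas_cols <- setdiff(seq_len(nc), stim_pair)
  mu <- apply(rows[, meas_cols, drop = FALSE], 2L, mean, na.rm = TRUE)
  sdv <- apply(rows[, meas_cols, drop = FALSE], 2L, stats::sd, na.rm = TRUE)
  simv <- sim[stim_pair, meas_cols]
  ok <- !is.na(mu) & !is.na(simv)
  if (!any(ok)) stop("empty overlap between simulation and measurements")
  lo <- mu[ok] - ifelse(is.na(sdv[ok]), 0, sdv[ok])
  hi <- mu[ok] + ifelse(is.na(sdv[ok]), 0, sdv[ok])
  within <- mean(simv[ok] >= lo & simv[ok] <= hi)
  structure(
    list(stim_pair = stim_pair, contacts = meas_cols[ok],
         mean = mu[ok], sd = sdv[ok], sim = simv[ok],
         within_band_fraction = within,
         bias = mean(simv[ok] - mu[ok]),
         n_subjects = nrow(rows)),
    class = "comparison_stats"
  )
}

#' @exportS3Method base::print
print.comparison_stats <- function(x, ...) {
  cat(sprintf("<comparison_stats> pair %d, %d subjects: %.0f%% within mean+/-1SD, bias %.3g V\n",
              x$stim_pair, x$n_subjects, 100 * x$within_band_fraction, x$bias))
  invisible(x)
}

#' Write a spread matrix / measurement set as CSV with a JSON sidecar
#'
#' CSV layout: header `contact,<id>,...`; one row per stimulating contact;
#' `NA` for masked entries and the diagonal. Metadata (subject, amplitude,
#' mask reasons, units) go to `<path>.json`. Values are written at full
#' precision so a write/read round trip is bit-exact.
#'
#' @param set a [measurement_set()] or `voltage_spread` matrix.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spread_csv <- function(set, path) {
  if (inherits(set, "voltage_spread")) {
    set <- measurement_set(unclass(set), subject = "simulation",
                           amplitude_uA = (attr(set, "amplitude_A") %||% 50e-6) * 1e6)
  }
  stopifnot(inherits(set, "measurement_set"))
  v <- set$values
  nc <- ncol(v)
  ids <- seq_len(nc)
  lines <- c(
    paste(c("contact", ids), collapse = ","),
    vapply(ids, function(i) {
      paste(c(i, ifelse(is.na(v[i, ]), "NA", sprintf("%.17g", v[i, ]))),
            collapse = ",")
    }, "")
  )
  writeLines(lines, path)
  mask <- which(is.na(v) & row(v) != col(v), arr.ind = TRUE)
  sidecar <- list(
    subject = set$subject, amplitude_uA = set$amplitude_uA,
    units = "V",
    mask = if (nrow(mask)) data.frame(
      stim = unname(mask[, 1L]), meas = unname(mask[, 2L]),
      reason = set$mask_reason[mask]
    ) else list()
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a spread-matrix CSV written by [write_spread_csv()]
#'
#' `NA` cells become masked entries; without a sidecar their reason defaults
#' to `"deactivated"`.
#'
#' @param path CSV path.
#' @return a [measurement_set()].
#' @export
read_spread_csv <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("format error at line 1: empty file")
  hdr <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (hdr[1L] != "contact" || length(hdr) < 3L)
    stop("format error at line 1: expected header 'contact,<id>,...'")
  nc <- length(hdr) - 1L
  if (length(lines) != nc + 1L)
    stop("format error at line ", length(lines),
         ": body has ", length(lines) - 1L, " rows for ", nc, " contacts")
  v <- matrix(NA_real_, nc, nc)
  for (i in seq_len(nc)) {
    f <- strsplit(lines[i + 1L], ",", fixed = TRUE)[[1L]]
    if (length(f) != nc + 1L)
      stop("format error at line ", i + 1L, ": expected ", nc + 1L, " fields")
    v[i, ] <- suppressWarnings(as.numeric(f[-1L]))
  }
  subject <- "unknown"
  amplitude <- 50
  reason <- matrix(NA_character_, nc, nc)
  reason[is.na(v) & row(v) != col(v)] <- "deactivated"
  sidefile <- paste0(path, ".json")
  if (file.exists(sidefile)) {
    side <- jsonlite::read_json(sidefile, simplifyVector = TRUE)
    subject <- side$subject %||% subject
    amplitude <- side$amplitude_uA %||% amplitude
    if (amplitude <= 0) stop("format error: negative or zero amplitude")
    if (is.data.frame(side$mask) && nrow(side$mask)) {
      reason[cbind(side$mask$stim, side$mask$meas)] <- side$mask$reason
    }
  }
  measurement_set(v, subject = subject, amplitude_uA = amplitude,
                  mask_reason = reason)
}
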