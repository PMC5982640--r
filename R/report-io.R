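profile_to_list <- function(p) {
  list(min_seg = attr(p, "min_seg") %||% 1L,
       states = lapply(seq_len(nrow(p)), function(i) as.list(p[i, ])))
}

profile_from_list <- function(x) {
  out <- do.call(rbind, lapply(x$states, function(r) as.data.frame(r)))
  class(out) <- c("state_profile", "data.frame")
  attr(out, "min_seg") <- as.integer(x$min_seg)
  out
}

#' Serialize a trained model registry to JSON
#'
#' Stores every entry's model, training statistics (minimum-window
#' likelihood distribution, thresholds, state profile), the registry
#' ratio statistics and the assessment configuration; a read/write round
#' trip restores a registry that assesses identically.
#'
#' @param registry A trained registry.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_registry_json <- function(registry, path) {
  entries <- lapply(registry$entries, function(e) {
    list(id = e$id, name = e$name, features = as.list(e$features),
         n_states = e$n_states, role = e$role,
         model = if (is.null(e$model)) NULL else hmm_to_list(e$model),
         stats = if (is.null(e$stats)) NULL else list(
           min_liks = e$stats$min_liks,
           good_threshold = e$stats$good_threshold,
           fair_threshold = e$stats$fair_threshold,
           profile = profile_to_list(e$stats$profile)))
  })
  jsonlite::write_json(
    list(format = "rehabmm-registry", version = HMM_FORMAT_VERSION,
         config = unclass(registry$config), entries = entries,
         ratio_stats = registry$ratio_stats, held_out = registry$held_out,
         training_trials = registry$training_trials),
    path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Read a trained model registry from JSON
#'
#' @param path Path written by [write_registry_json()].
#' @return A `model_registry`.
#' @export
read_registry_json <- function(path) {
  if (!file.exists(path)) rehab_error(paste0("no such file: ", path), "rehabmm_io_error")
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(x$format, "rehabmm-registry"))
    rehab_error("not a serialized model registry", "rehabmm_io_error")
  cfg <- do.call(assessment_config, x$config)
  entries <- lapply(x$entries, function(e) {
    out <- registry_entry(e$id, e$name, unlist(e$features), e$n_states, e$role)
    if (!is.null(e$model)) out$model <- hmm_from_list(e$model)
    if (!is.null(e$stats))
      out$stats <- list(min_liks = unlist(e$stats$min_liks),
                        good_threshold = e$stats$good_threshold,
                        fair_threshold = e$stats$fair_threshold,
                        profile = profile_from_list(e$stats$profile))
    out
  })
  names(entries) <- vapply(entries, `[[`, character(1), "id")
  reg <- structure(list(entries = entries, config = cfg), class = "model_registry")
  if (!is.null(x$ratio_stats))
    reg$ratio_stats <- lapply(x$ratio_stats, unlist)
  reg$held_out <- x$held_out
  reg$training_trials <- unlist(x$training_trials)
  reg
}

#' Serialize a movement assessment report to JSON
#'
#' Per-model total and per-frame log-likelihoods, window traces, Viterbi
#' paths as run-length `(state, length)` pairs, ratios, flags, outcome
#' and the configuration the numbers were produced under.
#'
#' @param assessment A [classify_movement()] result.
#' @param path Output path.
#' @param seed Seed to echo into the report header (audit).
#' @return `path`, invisibly.
#' @export
write_assessment_json <- function(assessment, path, seed = NULL) {
  rle_pairs <- function(states) {
    r <- rle(states)
    lapply(seq_along(r$values), function(i) c(r$values[i], r$lengths[i]))
  }
  per_model <- lapply(assessment$per_model, function(p) {
    if (!is.null(p$error)) return(list(id = p$id, error = p$error))
    list(id = p$id, loglik = p$loglik, loglik_per_frame = p$loglik_per_frame,
         window_starts = p$trace$window_starts, window_len = p$trace$window_len,
         stride = p$trace$stride, window_values = p$trace$values,
         viterbi_rle = rle_pairs(p$path$states))
  })
  jsonlite::write_json(
    list(format = "rehabmm-assessment", version = HMM_FORMAT_VERSION,
         seed = seed, config = unclass(assessment$config),
         outcome = assessment$outcome,
         symmetry = assessment$symmetry, synchronicity = assessment$synchronicity,
         clip = if (is.null(assessment$clip)) NULL else unclass(assessment$clip),
         flags = assessment$flags, per_model = per_model),
    path, auto_unbox = TRUE, digits = I(17), null = "null", dataframe = "rows")
  invisible(path)
}

#' Printed per-trial timing ratios of the reference hip-abduction study
#'
#' The published synchronicity and symmetry ratios of three healthy
#' subjects over eight hip-abduction trials, as raw (display-form)
#' values; shipped as a plain-text fixture for the averaging-convention
#' checks and as example input for [report_ratio()].
#'
#' @return Data frame with columns `measure` (`synchronicity`/
#'   `symmetry`), `subject`, `trial`, `ratio`.
#' @export
hip_abduction_ratios <- function() {
  path <- system.file("extdata", "hip_abduction_ratios.csv", package = "rehabmm",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
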