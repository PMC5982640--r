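HMM_FORMAT_VERSION <- "1.0"

hmm_to_list <- function(model) {
  list(format = "rehabmm-gaussian-hmm", version = HMM_FORMAT_VERSION,
       n_states = model$n_states, feature_names = as.list(model$feature_names),
       initial = model$initial,
       transition = lapply(seq_len(model$n_states), function(i) model$transition[i, ]),
       means = lapply(seq_len(model$n_states), function(i) model$means[i, ]),
       variances = lapply(seq_len(model$n_states), function(i) model$variances[i, ]))
}

hmm_from_list <- function(x) {
  if (!identical(x$format, "rehabmm-gaussian-hmm"))
    rehab_error("not a serialized Gaussian HMM", "rehabmm_io_error")
  gaussian_hmm(unlist(x$initial),
               do.call(rbind, lapply(x$transition, unlist)),
               do.call(rbind, lapply(x$means, unlist)),
               do.call(rbind, lapply(x$variances, unlist)),
               unlist(x$feature_names))
}

#' Serialize a Gaussian HMM to JSON
#'
#' Full-precision structured text with a format-version tag; a
#' write/read round trip is bit-exact.
#'
#' @param model A [gaussian_hmm()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hmm_json <- function(model, path) {
  validate_gaussian_hmm(model)
  jsonlite::write_json(hmm_to_list(model), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a Gaussian HMM from JSON
#'
#' @param path Path written by [write_hmm_json()].
#' @return A [gaussian_hmm()].
#' @export
read_hmm_json <- function(path) {
  if (!file.exists(path)) rehab_error(paste0("no such file: ", path), "rehabmm_io_error")
  hmm_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}
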