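#' Long-format tract-profile table schema
#'
#' Profiles are exchanged as a long-format table with one row per
#' (subject, tract, hemisphere, node) and the four diffusion metrics as
#' columns. Diffusivities are in mm^2/s; FA is unitless.
#'
#' @format columns `subject_id`, `group`, `tract`, `hemisphere`,
#'   `node` (integer, 1..n_nodes), `fa`, `md`, `ad`, `rd`.
#' @name profile_schema
NULL

.profile_cols <- c("subject_id", "group", "tract", "hemisphere", "node",
                   "fa", "md", "ad", "rd")

#' Save tract profiles to CSV
#'
#' @param profiles data frame in the [profile_schema] layout.
#' @param path output CSV path.
#' @export
save_profiles <- function(profiles, path) {
  miss <- setdiff(.profile_cols, names(profiles))
  if (length(miss) > 0L)
    stop("profile_schema_error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  utils::write.csv(profiles[, .profile_cols], path, row.names = FALSE)
  invisible(path)
}

#' Load tract profiles from CSV
#'
#' @param path CSV written by [save_profiles()].
#' @return data frame in the [profile_schema] layout.
#' @export
load_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.profile_cols, names(df))
  if (length(miss) > 0L)
    stop("profile_schema_error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$node <- as.integer(df$node)
  df[, .profile_cols]
}
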