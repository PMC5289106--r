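#' Read a sample table
#'
#' Reads a tab-separated sample table with columns `sample_id`, `group`,
#' `lat`, `lon`, `role` (ingroup/outgroup). Adds bookkeeping columns
#' `excluded` (FALSE) and `reassigned_from` (NA) used by
#' [apply_sample_rules()].
#'
#' @param path path to the TSV file.
#' @return a data frame of class `sample_table`.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  as_sample_table(tab)
}

#' Validate a data frame as a sample table
#'
#' @param tab data frame with columns `sample_id`, `group`, `lat`, `lon`,
#'   `role`.
#' @return the validated `sample_table`.
#' @export
as_sample_table <- function(tab) {
  need <- c("sample_id", "group", "lat", "lon", "role")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("sample table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample ids", call. = FALSE)
  if (!all(tab$role %in% c("ingroup", "outgroup")))
    stop("role must be 'ingroup' or 'outgroup'", call. = FALSE)
  ok_lat <- is.na(tab$lat) | (tab$lat >= -90 & tab$lat <= 90)
  ok_lon <- is.na(tab$lon) | (tab$lon >= -180 & tab$lon <= 180)
  if (!all(ok_lat & ok_lon)) stop("coordinates out of range", call. = FALSE)
  ing <- tab$role == "ingroup"
  if (any(ing & (is.na(tab$group) | tab$group == "")))
    stop("every ingroup sample needs a catchment group", call. = FALSE)
  if (is.null(tab$excluded)) tab$excluded <- FALSE
  if (is.null(tab$reassigned_from)) tab$reassigned_from <- NA_character_
  class(tab) <- c("sample_table", "data.frame")
  tab
}

#' Define sample reassignment and exclusion rules
#'
#' Samples collected within a few kilometres of a watershed can carry the
#' neighbouring catchment's genetic signature (mis-delineation or recent
#' migration) and are reassigned; contact-zone samples with conflicting
#' locus signals are excluded from all analyses. Rules are explicit sample
#' lists; the watershed distance is documentation of the criterion, not a
#' computed filter.
#'
#' @param reassignments data frame with columns `sample_id`, `new_group`,
#'   `reason` (or NULL).
#' @param exclusions data frame with columns `sample_id`, `reason` (or NULL).
#' @param watershed_distance_km documented proximity criterion (default 5).
#' @return an object of class `rule_set`.
#' @export
rule_set <- function(reassignments = NULL, exclusions = NULL,
                     watershed_distance_km = 5) {
  re <- if (is.null(reassignments))
    data.frame(sample_id = character(0), new_group = character(0),
               reason = character(0))
  else as.data.frame(reassignments)
  ex <- if (is.null(exclusions))
    data.frame(sample_id = character(0), reason = character(0))
  else as.data.frame(exclusions)
  both <- intersect(re$sample_id, ex$sample_id)
  if (length(both))
    stop("samples both reassigned and excluded: ",
         paste(both, collapse = ", "), call. = FALSE)
  structure(list(reassignments = re, exclusions = ex,
                 watershed_distance_km = watershed_distance_km),
            class = "rule_set")
}

#' Apply reassignment and exclusion rules to a sample table
#'
#' Reassignments change `group` and record the original in
#' `reassigned_from`; exclusions set `excluded = TRUE`. Rows are flagged,
#' never deleted, and the input table is left unchanged.
#'
#' @param table a `sample_table`.
#' @param rules a [rule_set()].
#' @return a new `sample_table` with rules applied.
#' @export
apply_sample_rules <- function(table, rules) {
  stopifnot(inherits(rules, "rule_set"))
  ids <- c(rules$reassignments$sample_id, rules$exclusions$sample_id)
  unknown <- setdiff(ids, table$sample_id)
  if (length(unknown))
    stop("configuration error: unknown sample id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  out <- table
  if (nrow(rules$reassignments)) {
    idx <- match(rules$reassignments$sample_id, out$sample_id)
    out$reassigned_from[idx] <- out$group[idx]
    out$group[idx] <- rules$reassignments$new_group
  }
  if (nrow(rules$exclusions)) {
    out$excluded[match(rules$exclusions$sample_id, out$sample_id)] <- TRUE
  }
  out
}

# active (ingroup, non-excluded) sample ids
.active_samples <- function(table) {
  table$sample_id[table$role == "ingroup" & !table$excluded]
}
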