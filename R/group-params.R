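#' Load the default generative group parameters
#'
#' Reads the parameter file shipped with the package: per-diagnosis group
#' sizes (PPPD 92, CDA 44, UVH 31, UD 37, plus an excluded "OTHER" stratum
#' of 27), per-item group means/SDs with the per-item available n
#' (missingness pattern), derived-total reference values, and the vHIT
#' sub-cohort parameters (56 PPPD / 6 UVH, catch-up-saccade counts 1 and 3).
#'
#' @param path Optional path to an alternative JSON parameter file with the
#'   same structure.
#' @return A named list of class `"group_params"`.
#' @export
default_group_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "group_params.json",
                        package = "vestscreen", mustWork = TRUE)
  params <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(params) <- "group_params"
  validate_group_params(params)
  params
}

#' Validate a group-parameter object
#'
#' Checks structural sanity: positive group sizes, non-negative SDs,
#' per-item available n within \[0, group size\], ranges ordered, vHIT
#' sub-cohort sizes within their group sizes and event counts within the
#' sub-cohort sizes.
#'
#' @param params A `group_params` list.
#' @return `params`, invisibly; errors describe the offending entry.
#' @export
validate_group_params <- function(params) {
  sizes <- unlist(params$group_sizes)
  if (any(sizes <= 0) || !all(c("PPPD", "CDA", "UVH", "UD") %in% names(sizes)))
    stop("group_sizes must be positive and include PPPD, CDA, UVH, UD",
         call. = FALSE)
  for (item in names(params$items)) {
    it <- params$items[[item]]
    if (it$range[1] >= it$range[2])
      stop(sprintf("item %s: range must be increasing", item), call. = FALSE)
    for (g in c("PPPD", "CDA", "UVH", "UD")) {
      cell <- it[[g]]
      if (is.null(cell))
        stop(sprintf("item %s: missing parameters for group %s", item, g),
             call. = FALSE)
      if (cell$sd < 0)
        stop(sprintf("item %s, group %s: sd must be non-negative", item, g),
             call. = FALSE)
      if (cell$n < 0 || cell$n > sizes[[g]])
        stop(sprintf("item %s, group %s: available n outside [0, group size]",
                     item, g), call. = FALSE)
    }
  }
  sub <- unlist(params$vhit$subcohort_sizes)
  if (any(sub > sizes[names(sub)]))
    stop("vHIT sub-cohort sizes exceed group sizes", call. = FALSE)
  cus <- unlist(params$vhit$cus_positive_counts)
  if (any(cus < 0 | cus > sub[names(cus)]))
    stop("vHIT catch-up-saccade counts outside [0, sub-cohort size]",
         call. = FALSE)
  invisible(params)
}

# Items analysed in the group-comparison screen: every distributed item plus
# the structurally derived questionnaire totals.
#' Names of the screened battery items
#'
#' All demographic, questionnaire and vestibular-test variables entering the
#' four-group Kruskal-Wallis screen, including the derived questionnaire
#' totals.
#'
#' @param params A `group_params` list.
#' @return Character vector of cohort column names.
#' @export
screened_items <- function(params = default_group_params()) {
  c(names(params$items), names(params$derived_totals))
}
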