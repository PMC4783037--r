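#' Packaged preference-elicitation fixtures
#'
#' The package ships structured-text transcriptions of an expert elicitation
#' for river rehabilitation assessment: the consolidated objectives
#' hierarchy, the attribute catalogue (numbered attributes with measures,
#' units and worst-to-best ranges), the level-1 weight/aggregation/synergy
#' table for five experts, the per-branch aggregation-method choices, and
#' synthetic certainty-equivalent sets reproducing the qualitative
#' risk-attitude pattern (the elicited CE values themselves were not
#' published in machine-readable form).
#'
#' The hierarchy file is named `*_synthetic.json` because the published
#' figure fixes the root, the three level-1 branches, the named level-2/3
#' objectives and the per-level counts (3/7/18/51/23), but not the complete
#' wiring below; the remaining structure is a reconstruction.
#'
#' @param file File name within the package's `extdata`; `NULL` lists the
#'   available files.
#' @return A file path (or a character vector of file names).
#' @examples
#' riverval_example()
#' @export
riverval_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "riverval")))
  }
  p <- system.file("extdata", file, package = "riverval", mustWork = FALSE)
  if (p == "") stop_riverval("no packaged file named ", file)
  p
}

#' Load the attribute catalogue
#'
#' One row per attribute record as printed: attribute numbers are kept
#' verbatim (number 24 was never printed and is absent; several numbers have
#' two or three expert-specific records distinguished by a source suffix on
#' the abbreviation). Columns: `number`, `abbreviation`, `measure`, `unit`,
#' `range` (the printed worst-best string), parsed `worst`/`best` (and
#' `worst2`/`best2` for the second limb of unimodal ranges), `discrete`,
#' `levels` (admissible levels of discrete attributes), `source` (expert id
#' or `"literature"`), `has_value_function`, and `flag` (records needing
#' review, e.g. two-limb ranges whose printed limbs peak at unequal levels).
#'
#' @param path CSV path; defaults to the packaged table.
#' @return A data frame.
#' @export
load_attribute_table <- function(path = riverval_example("attribute_table.csv")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(levels = "character", flag = "character"))
  df$discrete <- as.logical(df$discrete)
  df$has_value_function <- as.logical(df$has_value_function)
  for (col in c("worst", "best", "worst2", "best2")) df[[col]] <- as.numeric(df[[col]])
  df
}

#' Load the level-1 weight, aggregation and synergy table
#'
#' The published level-1 table: per-expert weights for the physical, chemical
#' and biological state, the chosen aggregation method, and the synergy
#' factor. Empty cells are the "no aggregation required" entries of the
#' expert who put full weight on the biological branch; they are returned as
#' `NA` and — unlike explicit 0 weights — never contribute to group medians.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return A list with `weights` (numeric matrix, objectives x experts),
#'   `aggregation` (named character, `NA` = not applicable) and `synergy`
#'   (named numeric, `NA` = not applicable).
#' @examples
#' t4 <- load_level1_table()
#' apply(t4$weights, 1, group_median)   # 0.28, 0.23, 0.45
#' group_median(t4$synergy)             # 0.75
#' @export
load_level1_table <- function(path = riverval_example("level1_weights.csv")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  experts <- names(raw)[-1]
  rows <- raw[[1]]
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  wrows <- !rows %in% c("aggregation", "synergy")
  weights <- t(vapply(which(wrows), function(i) num(unlist(raw[i, -1])),
                      numeric(length(experts))))
  dimnames(weights) <- list(rows[wrows], experts)
  agg <- unlist(raw[rows == "aggregation", -1])
  agg[agg == ""] <- NA
  list(weights = weights,
       aggregation = stats::setNames(as.character(agg), experts),
       synergy = stats::setNames(num(unlist(raw[rows == "synergy", -1])), experts))
}

#' Load the aggregation-method choices
#'
#' One row per aggregation decision (a node of some expert's hierarchy where
#' sub-objectives had to be combined), with the branch, the deciding expert
#' where stated, a short description and the chosen method.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return A data frame with columns `branch`, `expert`, `objective`,
#'   `method`.
#' @export
load_aggregation_choices <- function(path = riverval_example("aggregation_choices.csv")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Load the synthetic certainty-equivalent sets
#'
#' Three CE sets constructed to reproduce the qualitative risk pattern of
#' the elicited utility curves: all experts averse at the poor (0.25) and
#' good (0.75) states, one expert slightly prone at the moderate state.
#' The numeric CE values are synthetic stand-ins (the elicited values were
#' published only as curves).
#'
#' @param path JSON path; defaults to the packaged file.
#' @return A list of [ce_points()] objects.
#' @export
load_ce_sets <- function(path = riverval_example("ce_sets_synthetic.json")) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(doc, function(d) ce_points(d$x25, d$x50, d$x75, expert = d$expert))
}

#' @rdname load_hierarchy
#' @export
load_consolidated_hierarchy <- function() {
  load_hierarchy(riverval_example("hierarchy_consolidated_synthetic.json"))
}
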