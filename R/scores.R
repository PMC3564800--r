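# Allele-score construction.
#
# The weighted score multiplies each genotype count by its published
# per-allele weight and rescales by the sum of weights over the SNPs the
# cohort actually has, so the score stays on the 0-2 "average risk allele"
# scale whatever the missingness pattern.  Unweighted scores are plain risk
# allele counts and are only formed when every constituent SNP is present:
# a cohort missing any of them skips that score rather than imputing.

#' Define an allele score
#'
#' @param name Score label.
#' @param rsids SNP identifiers entering the score.
#' @param weights Per-SNP positive weights for a weighted score, or `NULL`
#'   for an unweighted (allele-count) score.
#' @return A list of class `score_def`.
#' @export
score_def <- function(name, rsids, weights = NULL) {
  stopifnot(is.character(name), length(rsids) >= 1)
  weighted <- !is.null(weights)
  if (weighted) {
    if (length(weights) != length(rsids)) {
      stop("weights and rsids must have equal length")
    }
    if (any(!is.finite(weights)) || any(weights <= 0)) {
      stop("score weights must all be positive")
    }
  }
  structure(list(name = name, rsids = as.character(rsids),
                 weights = weights, weighted = weighted),
            class = "score_def")
}

#' Standard score definitions from an instrument panel
#'
#' `bmi_score_def` builds the weighted 12-SNP BMI score (weights are the
#' panel's per-allele effects, positive under the BMI-raising allele
#' convention).  `synthesis_score_def` and `metabolism_score_def` build the
#' unweighted vitamin D scores from the synthesis (DHCR7, CYP2R1) and
#' metabolism (GC, CYP24A1) axes.
#'
#' @param panel An `snp_panel`.
#' @return A [score_def()].
#' @export
bmi_score_def <- function(panel) {
  i <- panel$axis == "bmi"
  score_def("bmi_score", panel$rsid[i], weights = panel$weight[i])
}

#' @rdname bmi_score_def
#' @export
synthesis_score_def <- function(panel) {
  score_def("synthesis_score", panel$rsid[panel$axis == "vitd_synthesis"])
}

#' @rdname bmi_score_def
#' @export
metabolism_score_def <- function(panel) {
  score_def("metabolism_score", panel$rsid[panel$axis == "vitd_metabolism"])
}

#' Compute per-subject allele scores for one cohort
#'
#' For a weighted score, SNPs whose genotype column is absent or entirely
#' missing in the cohort are dropped from both the numerator and the sum of
#' weights; if none remain an error is raised.  For an unweighted score any
#' missing constituent SNP causes the score to be skipped for the cohort
#' (returns `NULL` with a warning), matching the analysis-plan rule of not
#' imputing score components.
#'
#' @param table Cohort table with genotype columns named by rsid.
#' @param score A [score_def()].
#' @return Numeric vector of per-subject scores (weighted scores lie in
#'   \[0, 2\]; unweighted scores are integers in \[0, 2k\]), or `NULL` when
#'   an unweighted score is skipped.
#' @export
#' @examples
#' tab <- data.frame(rs1 = c(2, 0), rs2 = c(0, 1))
#' allele_score(tab, score_def("demo", c("rs1", "rs2"), weights = c(1, 3)))
allele_score <- function(table, score) {
  stopifnot(inherits(score, "score_def"))
  present <- vapply(score$rsids, function(rs) {
    rs %in% names(table) && !all(is.na(table[[rs]]))
  }, NA)
  if (score$weighted) {
    if (!any(present)) {
      stop("all SNPs of score '", score$name, "' are missing in this cohort")
    }
    rs <- score$rsids[present]
    w <- score$weights[present]
    g <- as.matrix(table[, rs, drop = FALSE])
    as.vector(g %*% w) / sum(w)
  } else {
    if (!all(present)) {
      warning("score '", score$name, "' skipped: missing SNP(s) ",
              paste(score$rsids[!present], collapse = ", "))
      return(NULL)
    }
    rowSums(table[, score$rsids, drop = FALSE])
  }
}
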