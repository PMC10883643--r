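## Docking difficulty classification and benchmark composition ----------
##
## Rigid:     I-RMSD < 1.5 A and f_non-nat < 0.40
## Difficult: I-RMSD > 2.2 A
## Medium:    everything else
## (strict inequalities; the three regions partition the quarter-plane).

#' Classification criteria
#'
#' @param rigid_irmsd_max,rigid_fnn_max,difficult_irmsd_min thresholds; the
#'   defaults are the standard values 1.5 A, 0.40 and 2.2 A.
#' @return list of class `abag_criteria`.
#' @export
classification_criteria <- function(rigid_irmsd_max = 1.5,
                                    rigid_fnn_max = 0.40,
                                    difficult_irmsd_min = 2.2) {
  if (!(rigid_irmsd_max < difficult_irmsd_min))
    stop("rigid_irmsd_max must be below difficult_irmsd_min")
  structure(list(rigid_irmsd_max = rigid_irmsd_max,
                 rigid_fnn_max = rigid_fnn_max,
                 difficult_irmsd_min = difficult_irmsd_min),
            class = "abag_criteria")
}

#' Classify docking difficulty
#'
#' Rigid when the entire-interface I-RMSD is below 1.5 A and f_non-nat
#' below 0.40; Difficult when I-RMSD exceeds 2.2 A; Medium otherwise.
#' Vectorized.
#'
#' @param i_rmsd entire-interface I-RMSD in Angstrom (non-negative).
#' @param f_non_nat fraction of non-native contacts in `[0,1]`.
#' @param criteria see [classification_criteria()].
#' @return character vector of labels `"Rigid"`, `"Medium"`, `"Difficult"`.
#' @export
classify_case <- function(i_rmsd, f_non_nat,
                          criteria = classification_criteria()) {
  if (any(is.na(i_rmsd)) || any(is.na(f_non_nat)))
    stop("i_rmsd and f_non_nat must be finite")
  if (any(i_rmsd < 0) || any(f_non_nat < 0))
    stop("i_rmsd and f_non_nat must be non-negative")
  out <- rep("Medium", length(i_rmsd))
  out[i_rmsd < criteria$rigid_irmsd_max &
        f_non_nat < criteria$rigid_fnn_max] <- "Rigid"
  out[i_rmsd > criteria$difficult_irmsd_min] <- "Difficult"
  out
}

DIFFICULTY_LEVELS <- c("Rigid", "Medium", "Difficult")
ANTIBODY_TYPES <- c("sdAb", "mAb")

#' Benchmark composition summary
#'
#' Category and antibody-type counts with the percentage arithmetic of a
#' benchmark composition table: category shares of the total and category
#' shares within each antibody type, all to two decimals (round half up).
#'
#' @param counts 3 x 2 matrix (rows Rigid/Medium/Difficult, columns
#'   sdAb/mAb) or a data.frame of labeled entries via
#'   [summarize_benchmark()].
#' @return object of class `abag_summary`: `counts`, `total`,
#'   `category_pct` (share of total per category), `type_category_pct`
#'   (per antibody type, share of that type's cases per category).
#' @export
benchmark_summary <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(DIFFICULTY_LEVELS %in% rownames(counts)) ||
      !all(ANTIBODY_TYPES %in% colnames(counts)))
    stop("counts must have rows Rigid/Medium/Difficult and columns sdAb/mAb")
  counts <- counts[DIFFICULTY_LEVELS, ANTIBODY_TYPES]
  total <- sum(counts)
  category <- rowSums(counts)
  structure(list(
    counts = counts, total = total,
    category_pct = percent_share(category, total),
    type_category_pct = apply(counts, 2, function(cl)
      percent_share(cl, sum(cl)))
  ), class = "abag_summary")
}

#' Summarize a set of labeled cases
#'
#' @param entries data.frame with columns `case_id`, `difficulty`
#'   (Rigid/Medium/Difficult) and `antibody_type` (sdAb/mAb).
#' @return `abag_summary` (see [benchmark_summary()]).
#' @export
summarize_benchmark <- function(entries) {
  if (!nrow(entries)) stop("no cases to summarize")
  need <- c("case_id", "difficulty", "antibody_type")
  if (!all(need %in% names(entries)))
    stop("entries must have columns: ", paste(need, collapse = ", "))
  bad <- entries$case_id[is.na(entries$difficulty) |
                           !entries$difficulty %in% DIFFICULTY_LEVELS |
                           is.na(entries$antibody_type) |
                           !entries$antibody_type %in% ANTIBODY_TYPES]
  if (length(bad))
    stop("unlabeled or mis-labeled case(s): ", paste(bad, collapse = ", "))
  tab <- table(factor(entries$difficulty, levels = DIFFICULTY_LEVELS),
               factor(entries$antibody_type, levels = ANTIBODY_TYPES))
  benchmark_summary(unclass(tab))
}

#' @export
print.abag_summary <- function(x, ...) {
  cat(sprintf("Benchmark composition (%d cases)\n", x$total))
  m <- cbind(x$counts, All = rowSums(x$counts),
             `Share(%)` = x$category_pct)
  print(m)
  cat("Rigid share within type (%):",
      paste(sprintf("%s %.2f", ANTIBODY_TYPES,
                    vapply(ANTIBODY_TYPES, function(tp)
                      x$type_category_pct[["Rigid", tp]], numeric(1))),
            collapse = ", "), "\n")
  invisible(x)
}

#' Compare two benchmark versions
#'
#' Per-field percent increase `(new - old) / old * 100`, two decimals,
#' round half up; fields with an old count of zero are reported `NA`.
#'
#' @param old,new named numeric vectors of counts (same field names), or
#'   `abag_summary` objects (compared on All + category counts).
#' @return data.frame `field`, `old`, `new`, `increase_pct`.
#' @export
compare_versions <- function(old, new) {
  as_counts <- function(s) {
    if (inherits(s, "abag_summary"))
      c(All = s$total, rowSums(s$counts))
    else unlist(s)
  }
  old <- as_counts(old); new <- as_counts(new)
  if (!setequal(names(old), names(new)))
    stop("old and new summaries have different field sets")
  new <- new[names(old)]
  inc <- ifelse(old > 0, round_half_up((new - old) / old * 100, 2), NA_real_)
  data.frame(field = names(old), old = as.numeric(old),
             new = as.numeric(new), increase_pct = as.numeric(inc),
             stringsAsFactors = FALSE)
}

#' Write a composition summary as CSV
#' @param summary `abag_summary`.
#' @param path CSV path.
#' @export
write_benchmark_summary <- function(summary, path) {
  df <- data.frame(
    category = rownames(summary$counts),
    sdAb = summary$counts[, "sdAb"],
    mAb = summary$counts[, "mAb"],
    all = rowSums(summary$counts),
    share_pct = summary$category_pct
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
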