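# Fold-change differential expression, expression-profile classes and
# coregulation scoring on FPKM tables.
#
# Sample columns are keyed condition_timepoint_replicate, e.g.
# "regeneration_early_1". Conditions are {control, regeneration}; timepoints
# {early, mid, late}.

TIMEPOINTS <- c("early", "mid", "late")
CONDITIONS <- c("control", "regeneration")

#' Read an FPKM expression table
#'
#' @param path tab-delimited file with header; first column `gene_id`, one
#'   column per sample keyed `condition_timepoint_rep`.
#' @return expression data frame.
#' @export
read_expression <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (names(x)[1] != "gene_id") stop("first column must be gene_id", call. = FALSE)
  if (any(as.matrix(x[, -1, drop = FALSE]) < 0))
    stop("FPKM values must be >= 0", call. = FALSE)
  x
}

#' Write an FPKM expression table
#' @param x expression data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# decompose sample column names into (condition, timepoint, replicate)
parse_sample_keys <- function(keys) {
  parts <- strsplit(keys, "_", fixed = TRUE)
  bad <- lengths(parts) != 3
  if (any(bad))
    stop("sample key(s) not of the form condition_timepoint_rep: ",
         paste(keys[bad], collapse = ", "), call. = FALSE)
  data.frame(key = keys,
             condition = vapply(parts, `[`, character(1), 1),
             timepoint = vapply(parts, `[`, character(1), 2),
             replicate = vapply(parts, `[`, character(1), 3),
             stringsAsFactors = FALSE)
}

#' Per-gene mean FPKM for one condition and timepoint
#'
#' Replicates are combined by arithmetic mean.
#'
#' @param expr expression data frame ([read_expression()]).
#' @param condition `"control"` or `"regeneration"`.
#' @param timepoint `"early"`, `"mid"` or `"late"`.
#' @return named numeric vector (names are gene ids).
#' @export
expression_means <- function(expr, condition, timepoint) {
  keys <- parse_sample_keys(setdiff(names(expr), "gene_id"))
  cols <- keys$key[keys$condition == condition & keys$timepoint == timepoint]
  if (!length(cols))
    stop("no samples for condition '", condition, "' at timepoint '",
         timepoint, "'", call. = FALSE)
  m <- rowMeans(as.matrix(expr[, cols, drop = FALSE]))
  names(m) <- expr$gene_id
  m
}

#' Call differential expression by fold change
#'
#' Replicate FPKMs are averaged per condition; a gene is up-regulated when
#' the pseudocounted regeneration/control ratio reaches `fc`, down-regulated
#' when it falls below `1/fc`, and not differentially expressed (nde)
#' otherwise. The default 1.7-fold cutoff is the threshold used throughout
#' the damage-response analyses in this package.
#'
#' @param expr expression data frame.
#' @param timepoint timepoint to compare.
#' @param fc fold-change threshold (default 1.7).
#' @param pseudocount added to both condition means before the ratio
#'   (default 0.01), so zero-FPKM genes are well defined.
#' @return data frame with `gene_id`, `timepoint`, `mean_control`,
#'   `mean_regeneration`, `fold_change`, `direction`.
#' @export
call_de <- function(expr, timepoint, fc = 1.7, pseudocount = 0.01) {
  mc <- expression_means(expr, "control", timepoint)
  mr <- expression_means(expr, "regeneration", timepoint)
  fold <- (mr + pseudocount) / (mc + pseudocount)
  direction <- ifelse(fold >= fc, "up", ifelse(fold <= 1 / fc, "down", "nde"))
  data.frame(gene_id = expr$gene_id, timepoint = timepoint,
             mean_control = unname(mc), mean_regeneration = unname(mr),
             fold_change = unname(fold), direction = unname(direction),
             stringsAsFactors = FALSE)
}

#' Classify a three-timepoint expression profile
#'
#' A gene is `variable` when its max/min FPKM ratio (pseudocounted) exceeds
#' 2; otherwise the class follows the mean over the three timepoints:
#' `high` (> 30 FPKM), `moderate` (> 5 and <= 30), `low` (> 1 and <= 5),
#' `silenced` (<= 1).
#'
#' @param fpkm numeric vector of exactly three non-negative values
#'   (early, mid, late).
#' @param pseudocount added to max and min before the ratio (default 0.01).
#' @return one of `"variable"`, `"high"`, `"moderate"`, `"low"`, `"silenced"`.
#' @export
classify_profile <- function(fpkm, pseudocount = 0.01) {
  if (length(fpkm) != 3L || anyNA(fpkm))
    stop("profile needs exactly three FPKM values", call. = FALSE)
  if (any(fpkm < 0)) stop("FPKM must be >= 0", call. = FALSE)
  if ((max(fpkm) + pseudocount) / (min(fpkm) + pseudocount) > 2) return("variable")
  m <- mean(fpkm)
  if (m > 30) "high" else if (m > 5) "moderate" else if (m > 1) "low" else "silenced"
}

#' Profile classes for all genes of one condition
#'
#' @param expr expression data frame.
#' @param condition condition whose per-timepoint means are classified.
#' @param pseudocount see [classify_profile()].
#' @return data frame with `gene_id` and `profile_class`.
#' @export
classify_profiles <- function(expr, condition = "regeneration", pseudocount = 0.01) {
  mat <- vapply(TIMEPOINTS, function(tp) expression_means(expr, condition, tp),
                numeric(nrow(expr)))
  data.frame(gene_id = expr$gene_id,
             profile_class = apply(mat, 1, classify_profile, pseudocount = pseudocount),
             stringsAsFactors = FALSE)
}

#' Pearson coregulation of two expression profiles
#'
#' Correlation of `log(FPKM + pseudocount)` across matched timepoints.
#' Undefined (returned as `NA`) when either log-profile has zero variance.
#'
#' @param a,b numeric vectors of per-timepoint FPKM (same length, >= 3).
#' @param pseudocount added before the log (default 0.01).
#' @return Pearson r, or `NA_real_`.
#' @export
coregulation <- function(a, b, pseudocount = 0.01) {
  if (length(a) != length(b) || length(a) < 3L)
    stop("profiles must have equal length >= 3", call. = FALSE)
  la <- log(a + pseudocount)
  lb <- log(b + pseudocount)
  if (stats::sd(la) == 0 || stats::sd(lb) == 0) return(NA_real_)
  stats::cor(la, lb)
}
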