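COUNT_COLS <- c("position", "wt_aa", "mut_aa", "var_class", "condition",
                "replicate", "timepoint", "count")

#' Write a long-format count table to TSV
#'
#' @param counts count table (one or more conditions stacked).
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  miss <- setdiff(COUNT_COLS, names(counts))
  if (length(miss)) stop_input("count table missing column(s): %s",
                               paste(miss, collapse = ", "))
  met_write_tsv(counts[, COUNT_COLS], path, digits = 10)
}

#' Read and validate a long-format count TSV
#'
#' Enforces the count-file contract: exact column set, nonnegative counts,
#' no duplicate (variant, replicate, timepoint) cells, and a complete
#' replicate x timepoint grid per variant within each condition — a missing
#' cell is an error, never an implicit zero. Errors cite the offending data
#' row number (header = row 1).
#'
#' @param path counts TSV path.
#' @return named list with one count table per condition present (empty
#'   list for a header-only file).
#' @export
read_counts <- function(path) {
  df <- met_read_tsv(path)
  miss <- setdiff(COUNT_COLS, names(df))
  if (length(miss)) stop_input("malformed header in %s: missing %s", path,
                               paste(miss, collapse = ", "))
  df <- df[, COUNT_COLS]
  if (!nrow(df)) return(structure(list(), names = character(0)))
  if (!is.numeric(df$count)) stop_input("non-numeric count column in %s", path)
  neg <- which(df$count < 0)
  if (length(neg)) stop_input("negative count at row %d of %s", neg[1] + 1, path)
  key <- paste(df$position, df$mut_aa, df$condition, df$replicate,
               df$timepoint, sep = "|")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop_input("duplicate (variant, replicate, timepoint) cell at row %d of %s",
               dup[1] + 1, path)
  }
  out <- split(df, df$condition)
  for (cond in names(out)) {
    tab <- out[[cond]]
    reps <- sort(unique(tab$replicate))
    tps <- sort(unique(tab$timepoint))
    cells <- table(paste(tab$position, tab$mut_aa, sep = "|"))
    expect <- length(reps) * length(tps)
    bad <- names(cells)[cells != expect]
    if (length(bad)) {
      stop_input("condition '%s': variant %s has %d of %d (replicate, timepoint) cells",
                 cond, bad[1], cells[[bad[1]]], expect)
    }
    rownames(tab) <- NULL
    out[[cond]] <- tab
  }
  out
}

#' Filter variants by count-support thresholds
#'
#' Keeps a variant iff (i) its mean count over all replicate x timepoint
#' cells is at least `mean_min`, (ii) the fraction of zero cells over all
#' R x T cells is at most `zero_frac_max`, and (iii) the fraction of zero
#' cells among the replicate cells at timepoint 0 (harvested before
#' inhibitor selection) is at most `zero_frac_t0_max`. All thresholds are
#' inclusive; boundary values pass. Filtering is per condition.
#'
#' @param counts count table for a single condition.
#' @param mean_min minimum mean count (default 4).
#' @param zero_frac_max maximum overall zero-cell fraction (default 10/12).
#' @param zero_frac_t0_max maximum zero fraction at T0 (default 2/3).
#' @return list with `counts` (kept rows) and `report` (per-variant
#'   `mean_count`, `zero_fraction_all`, `zero_fraction_t0`, `kept`,
#'   `reason` — the first failing rule, or `""`).
#' @export
filter_variants <- function(counts, mean_min = 4, zero_frac_max = 10 / 12,
                            zero_frac_t0_max = 2 / 3) {
  if (!nrow(counts)) stop_input("empty count table")
  if (length(unique(counts$condition)) != 1) {
    stop_input("filter_variants expects a single condition; got %d",
               length(unique(counts$condition)))
  }
  key <- paste0(counts$wt_aa, counts$position, counts$mut_aa)
  mean_count <- tapply(counts$count, key, mean)
  zero_all <- tapply(counts$count == 0, key, mean)
  at_t0 <- counts$timepoint == min(counts$timepoint)
  zero_t0 <- tapply(counts$count[at_t0] == 0, key[at_t0], mean)
  vids <- names(mean_count)
  zero_t0 <- zero_t0[vids]
  ok_mean <- mean_count >= mean_min
  ok_zero <- zero_all <= zero_frac_max
  ok_t0 <- zero_t0 <= zero_frac_t0_max
  kept <- ok_mean & ok_zero & ok_t0
  reason <- rep("", length(vids))
  reason[!ok_t0] <- "high_t0_zero_fraction"
  reason[!ok_zero] <- "high_zero_fraction"
  reason[!ok_mean] <- "low_mean_count"
  first <- counts[!duplicated(key), c("position", "wt_aa", "mut_aa",
                                      "var_class", "condition")]
  first <- first[match(vids, paste0(first$wt_aa, first$position, first$mut_aa)), ]
  report <- data.frame(first,
                       mean_count = as.numeric(mean_count),
                       zero_fraction_all = as.numeric(zero_all),
                       zero_fraction_t0 = as.numeric(zero_t0),
                       kept = as.logical(kept),
                       reason = reason,
                       stringsAsFactors = FALSE)
  rownames(report) <- NULL
  keep_rows <- counts[kept[key], , drop = FALSE]
  rownames(keep_rows) <- NULL
  list(counts = keep_rows, report = report)
}
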