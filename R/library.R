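#' Build a saturation-mutagenesis variant library
#'
#' Enumerates, for a contiguous protein region, every single amino-acid
#' substitution (19 missense + 1 synonymous per position) plus an early-stop
#' nonsense control every `stop_spacing` positions starting at
#' `region_start`. This mirrors a one-codon-per-amino-acid designed library
#' with evenly spaced stop controls.
#'
#' @param region_start,region_end first and last residue (1-based protein
#'   numbering, inclusive), e.g. 1059 and 1345 for a kinase domain plus a
#'   short juxtamembrane stretch.
#' @param wt_sequence one-letter wild-type sequence of the region; its length
#'   must equal `region_end - region_start + 1`.
#' @param stop_spacing spacing of nonsense controls in residues (default 11).
#' @return data frame with columns `position`, `wt_aa`, `mut_aa`,
#'   `var_class` (missense/synonymous/nonsense), ordered by position then
#'   alphabetical `mut_aa` with `"*"` last.
#' @examples
#' lib <- build_library(1, 2, "AC", stop_spacing = 2)
#' nrow(lib)  # 41: 2 x 20 substitutions + 1 stop at position 1
#' @export
build_library <- function(region_start, region_end, wt_sequence,
                          stop_spacing = 11) {
  if (region_end < region_start) {
    stop_input("region_end (%s) < region_start (%s)", region_end, region_start)
  }
  if (stop_spacing < 1) stop_input("stop_spacing must be >= 1")
  wt <- strsplit(toupper(wt_sequence), "")[[1]]
  n_pos <- region_end - region_start + 1
  if (length(wt) != n_pos) {
    stop_input("wt_sequence has %d residues but region %d-%d spans %d",
               length(wt), region_start, region_end, n_pos)
  }
  bad <- setdiff(unique(wt), AA_STANDARD)
  if (length(bad)) {
    stop_input("non-standard residue letter(s) in wt_sequence: %s",
               paste(bad, collapse = ", "))
  }
  positions <- region_start:region_end
  lib <- data.frame(
    position = rep(positions, each = length(AA_STANDARD)),
    wt_aa = rep(wt, each = length(AA_STANDARD)),
    mut_aa = rep(AA_STANDARD, n_pos),
    stringsAsFactors = FALSE
  )
  stop_pos <- positions[(positions - region_start) %% stop_spacing == 0]
  stops <- data.frame(
    position = stop_pos,
    wt_aa = wt[match(stop_pos, positions)],
    mut_aa = STOP_SYMBOL,
    stringsAsFactors = FALSE
  )
  lib <- rbind(lib, stops)
  lib$var_class <- ifelse(lib$mut_aa == STOP_SYMBOL, "nonsense",
                          ifelse(lib$mut_aa == lib$wt_aa, "synonymous",
                                 "missense"))
  # position, then alphabetical mutant with "*" last
  ord <- order(lib$position, lib$mut_aa == STOP_SYMBOL, lib$mut_aa)
  lib <- lib[ord, , drop = FALSE]
  rownames(lib) <- NULL
  lib
}

#' Define experimental conditions
#'
#' @param name condition names (e.g. `"DMSO"`, `"crizotinib"`).
#' @param inhibitor_type one of `"DMSO"`, `"I_a"`, `"I_b"`, `"II"`,
#'   `"I_half"`, `"III"` per condition.
#' @param wt_doublings_per_interval wild-type doublings between contiguous
#'   time points; the screen design holds this at 2 in every condition so
#'   scores are comparable across inhibitors.
#' @return data frame of condition metadata.
#' @export
make_conditions <- function(name, inhibitor_type,
                            wt_doublings_per_interval = 2) {
  allowed <- c("DMSO", "I_a", "I_b", "II", "I_half", "III")
  if (length(name) != length(inhibitor_type)) {
    stop_input("name and inhibitor_type lengths differ")
  }
  bad <- setdiff(inhibitor_type, allowed)
  if (length(bad)) stop_input("unknown inhibitor_type: %s",
                              paste(bad, collapse = ", "))
  if (sum(inhibitor_type == "DMSO") != 1) {
    stop_input("exactly one DMSO condition is required per experiment")
  }
  g <- rep_len(wt_doublings_per_interval, length(name))
  if (any(g <= 0)) stop_input("wt_doublings_per_interval must be > 0")
  data.frame(condition = name, inhibitor_type = inhibitor_type,
             wt_doublings_per_interval = g, stringsAsFactors = FALSE)
}
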