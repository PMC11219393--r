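#' Maximal open reading frame length
#'
#' Scans the three forward-strand reading frames for the longest
#' ATG-initiated, in-frame, stop-terminated segment and returns its length
#' in bp counting the start codon through the last sense codon (the stop is
#' excluded), so an open frame of 250 codons plus stop reports 750.
#' Alignment gaps (`-`) are removed before scanning; degenerate IUPAC codes
#' must be resolved first.
#'
#' @param nt_seq Nucleotide sequence: a single string or a character vector
#'   of single bases over `A/C/G/T/-`.
#' @return Longest ORF length in bp (0 if none).
#' @examples
#' max_orf_length(paste0("ATG", strrep("GCT", 249), "TAA"))  # 750
#' @export
max_orf_length <- function(nt_seq) {
  s <- as_base_vector(nt_seq)
  s <- s[s != "-"]
  if (any(!s %in% c("A", "C", "G", "T")))
    stop("degenerate codes present; resolve haplotypes first ",
         "(see resolve_degenerate)")
  best <- 0L
  for (f in 0:2) {
    starts <- seq.int(1L + f, length(s) - 2L, by = 3L)
    if (length(starts) == 0 || starts[1] > length(s) - 2L) next
    codons <- paste0(s[starts], s[starts + 1L], s[starts + 2L])
    open_at <- NA_integer_
    for (i in seq_along(codons)) {
      if (is.na(open_at) && codons[i] == "ATG") open_at <- i
      if (!is.na(open_at) && codons[i] %in% STOP_CODONS) {
        best <- max(best, 3L * (i - open_at))
        open_at <- NA_integer_
      }
    }
  }
  best
}

as_base_vector <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1]]
  toupper(x)
}

#' Count predicted transmembrane segments by hydropathy
#'
#' Deterministic stand-in for a transmembrane topology predictor: a
#' Kyte-Doolittle sliding-window scan. Window averages above the threshold
#' mark membrane-favorable positions; maximal runs of such window starts are
#' segments, and runs separated by fewer than `min_gap` below-threshold
#' windows are merged. Constants are declared defaults, not fitted.
#'
#' @param aa_seq Amino-acid sequence (string or character vector).
#'   Unknown residues (including `*`) score 0.
#' @param window Window width in residues.
#' @param threshold Mean-hydropathy threshold (strictly above).
#' @param min_gap Minimum number of below-threshold windows separating two
#'   segments.
#' @return Number of predicted membrane-spanning segments.
#' @export
count_tm_segments <- function(aa_seq, window = 19, threshold = 1.6,
                              min_gap = 3) {
  aa <- as_base_vector(aa_seq)
  if (length(aa) < window) return(0L)
  kd <- KD_SCALE[aa]
  kd[is.na(kd)] <- 0
  win <- vapply(seq_len(length(kd) - window + 1L),
                function(i) mean(kd[i:(i + window - 1L)]), numeric(1))
  above <- win > threshold
  if (!any(above)) return(0L)
  r <- rle(above)
  # merge above-runs separated by short below-runs
  if (length(r$lengths) > 2)
    for (i in seq(2, length(r$values) - 1L))
      if (!r$values[i] && r$lengths[i] < min_gap &&
          r$values[i - 1] && r$values[i + 1]) r$values[i] <- TRUE
  r2 <- rle(inverse.rle(r))
  sum(r2$values)
}

IUPAC_TWOFOLD <- list(M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
                      S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"))

#' Resolve IUPAC-degenerate haplotypes into two test pairs
#'
#' Unphased heterozygous sites appear as the same two-fold IUPAC code in
#' both putative haplotypes. Rather than testing all combinations across
#' sites exhaustively, exactly two resolved pairs are built: in the first
#' (`H1_1`/`H2_1`), H1 takes the alphabetically first nucleotide of each
#' code and H2 the second, at every degenerate site; in the second
#' (`H1_2`/`H2_2`) the assignment is the opposite at every site. A site
#' degenerate in only one haplotype is resolved the same way in that
#' haplotype alone.
#'
#' @param H1,H2 Haplotype sequences (strings or base vectors) possibly
#'   containing two-fold IUPAC codes. Three/four-fold codes (B, D, H, V, N)
#'   are rejected.
#' @return A list of class `resolved_quartet` with character-vector
#'   elements `H1_1`, `H2_1`, `H1_2`, `H2_2`.
#' @examples
#' q <- resolve_degenerate("ARGTYC", "ARGTYC")
#' paste(q$H1_1, collapse = "")  # A at R, C at Y
#' @export
resolve_degenerate <- function(H1, H2) {
  h1 <- as_base_vector(H1)
  h2 <- as_base_vector(H2)
  if (length(h1) != length(h2))
    stop("H1 and H2 must have equal length")
  bad <- union(setdiff(unique(h1), c("A", "C", "G", "T", "-", names(IUPAC_TWOFOLD))),
               setdiff(unique(h2), c("A", "C", "G", "T", "-", names(IUPAC_TWOFOLD))))
  if (length(bad))
    stop("unsupported codes (only two-fold IUPAC codes can be resolved): ",
         paste(bad, collapse = ", "))
  resolve <- function(h, which) {
    deg <- h %in% names(IUPAC_TWOFOLD)
    h[deg] <- vapply(h[deg], function(code) IUPAC_TWOFOLD[[code]][which],
                     character(1))
    h
  }
  structure(list(H1_1 = resolve(h1, 1L), H2_1 = resolve(h2, 2L),
                 H1_2 = resolve(h1, 2L), H2_2 = resolve(h2, 1L)),
            class = "resolved_quartet")
}

#' Intact/disrupted verdict for one unambiguous sequence
#'
#' A sequence is intact only if its maximal ORF is at least `min_orf` bp
#' (default 750, i.e. 250 amino acids) and the protein encoded by that ORF
#' is predicted to span the membrane the required number of times
#' (default exactly 7).
#'
#' @param nt_seq Unambiguous nucleotide sequence (gaps allowed, removed).
#' @param min_orf Minimum ORF length in bp.
#' @param tm_required Required number of predicted TM segments.
#' @param tm_mode `"exact"` (exactly `tm_required`) or `"min"` (at least).
#' @return A list: `orf_length`, `tm_count`, `status`
#'   (`"intact"`/`"disrupted"`).
#' @export
sequence_verdict <- function(nt_seq, min_orf = 750, tm_required = 7,
                             tm_mode = c("exact", "min")) {
  tm_mode <- match.arg(tm_mode)
  orf <- max_orf_length(nt_seq)
  tm <- 0L
  if (orf >= 3) {
    aa <- orf_protein(nt_seq, orf)
    tm <- count_tm_segments(aa)
  }
  tm_ok <- if (tm_mode == "exact") tm == tm_required else tm >= tm_required
  list(orf_length = orf, tm_count = tm,
       status = if (orf >= min_orf && tm_ok) "intact" else "disrupted")
}

# protein of the (first, longest) maximal ORF
orf_protein <- function(nt_seq, orf_len) {
  s <- as_base_vector(nt_seq)
  s <- s[s != "-"]
  for (f in 0:2) {
    starts <- seq.int(1L + f, length(s) - 2L, by = 3L)
    codons <- paste0(s[starts], s[starts + 1L], s[starts + 2L])
    open_at <- NA_integer_
    for (i in seq_along(codons)) {
      if (is.na(open_at) && codons[i] == "ATG") open_at <- i
      if (!is.na(open_at) && codons[i] %in% STOP_CODONS) {
        if (3L * (i - open_at) == orf_len) {
          nt <- s[(starts[open_at]):(starts[i - 1L] + 2L)]
          return(paste(seqinr::translate(nt), collapse = ""))
        }
        open_at <- NA_integer_
      }
    }
  }
  ""
}

#' Gene-level status from per-sequence verdicts
#'
#' All sequences intact gives an intact gene; all disrupted, a disrupted
#' gene. A mix of intact and disrupted sequences is a segregating
#' pseudogene when the locus is a single locus (the two forms are alleles),
#' but merely "intact and disrupted" for congregated or undecided loci
#' (categories 1, 3, 4), where allelic and paralogous origins cannot be
#' told apart.
#'
#' @param verdicts Character vector (or list of [sequence_verdict()]
#'   results) of `"intact"`/`"disrupted"` statuses for all evaluated
#'   sequences of the gene.
#' @param locus_call The gene's locus call (`"single_locus"`,
#'   `"duplicated_congregated"`, `"high_snp_only"`, ...).
#' @param category The locus category (`NA`, 1, 2, 3 or 4).
#' @return One of `"intact"`, `"disrupted"`, `"segregating_pseudogene"`,
#'   `"intact_and_disrupted"`.
#' @export
gene_status <- function(verdicts, locus_call = "single_locus",
                        category = NA) {
  if (is.list(verdicts))
    verdicts <- vapply(verdicts, function(v) v$status, character(1))
  if (length(verdicts) == 0) stop("no verdicts supplied")
  if (!all(verdicts %in% c("intact", "disrupted")))
    stop("verdicts must be 'intact' or 'disrupted'")
  if (all(verdicts == "intact")) return("intact")
  if (all(verdicts == "disrupted")) return("disrupted")
  if (!is.na(category) && category %in% c(1, 3, 4))
    return("intact_and_disrupted")
  "segregating_pseudogene"
}

#' Classify every gene of an emission given its locus calls
#'
#' For each gene locus: degenerate sites are resolved into the two test
#' pairs and all four sequences receive verdicts; without degenerate sites
#' only H1/H2 are tested (H1 alone when the alleles are identical). The
#' per-sequence ORF lengths and TM counts are reported alongside the
#' gene-level status.
#'
#' @param emission A [emit_capture()] result (or compatible `sequences`).
#' @param calls A [call_loci()] result.
#' @param min_orf,tm_required See [sequence_verdict()].
#' @return Data frame with one row per gene locus per species: locus call,
#'   category, `orf_*`/`tm_*` columns for H1-1, H2-1, H1-2, H2-2 (NA where
#'   not evaluated) and `status`.
#' @export
classify_genes <- function(emission, calls, min_orf = 750, tm_required = 7) {
  cl <- calls$calls
  cl <- cl[cl$call %in% c("single_locus", "duplicated_congregated",
                          "high_snp_only", "split_single_locus"), ]
  rows <- list()
  for (i in seq_len(nrow(cl))) {
    sp <- cl$species[i]
    id <- cl$locus_id[i]
    key <- paste(sp, id, sep = ":")
    sq <- emission$sequences[[key]]
    if (is.null(sq) && cl$call[i] == "split_single_locus") {
      # split children carry the sequence evidence; parent row is bookkeeping
      next
    }
    if (is.null(sq)) {
      # child of a split: fall back to the parent's pair
      parent <- sub("-[12]$", "", id)
      pk <- paste(sp, parent, sep = ":")
      side <- if (grepl("-2$", id)) "H2" else "H1"
      sq <- list(H1 = emission$sequences[[pk]][[side]],
                 H2 = emission$sequences[[pk]][[side]])
    }
    has_deg <- any(c(sq$H1, sq$H2) %in% names(IUPAC_TWOFOLD))
    q <- resolve_degenerate(sq$H1, sq$H2)
    seqs <- if (has_deg) q[c("H1_1", "H2_1", "H1_2", "H2_2")]
            else if (!identical(sq$H1, sq$H2)) q[c("H1_1", "H2_1")]
            else q["H1_1"]
    vd <- lapply(seqs, sequence_verdict, min_orf = min_orf,
                 tm_required = tm_required)
    row <- data.frame(species = sp, gene_id = id, locus_call = cl$call[i],
                      category = cl$category[i],
                      orf_H1_1 = NA_integer_, tm_H1_1 = NA_integer_,
                      orf_H2_1 = NA_integer_, tm_H2_1 = NA_integer_,
                      orf_H1_2 = NA_integer_, tm_H1_2 = NA_integer_,
                      orf_H2_2 = NA_integer_, tm_H2_2 = NA_integer_)
    for (nm in names(vd)) {
      row[[paste0("orf_", gsub("H(\\d)_(\\d)", "H\\1_\\2", nm))]] <-
        vd[[nm]]$orf_length
      row[[paste0("tm_", nm)]] <- vd[[nm]]$tm_count
    }
    row$status <- gene_status(vd, cl$call[i], cl$category[i])
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}
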