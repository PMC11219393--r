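#' Median-inclusive boxplot summary
#'
#' Five-number summary with the quartile convention used throughout the
#' depth/SNP screening: quartiles are Tukey hinges computed with the median
#' included in both halves for odd sample sizes, and whiskers are the most
#' extreme data points within 1.5 interquartile ranges of the quartiles
#' (whiskers are data points, not fences).
#'
#' @param values Numeric vector, length >= 1.
#' @return A list of class `boxplot_summary`: `q1`, `median`, `q3`, `iqr`,
#'   `lower_whisker`, `upper_whisker`, `n`.
#' @examples
#' boxplot_stats(c(1:10, 100))
#' @export
boxplot_stats <- function(values) {
  if (length(values) == 0) stop("'values' must be non-empty")
  if (anyNA(values)) stop("'values' must not contain NA")
  x <- sort(values)
  n <- length(x)
  half <- if (n %% 2 == 1) (n + 1L) / 2L else n / 2L
  lower <- x[seq_len(half)]
  upper <- x[seq.int(n - half + 1L, n)]
  q1 <- stats::median(lower)
  q3 <- stats::median(upper)
  iqr <- q3 - q1
  lw <- min(x[x >= q1 - 1.5 * iqr])
  uw <- max(x[x <= q3 + 1.5 * iqr])
  structure(list(q1 = q1, median = stats::median(x), q3 = q3, iqr = iqr,
                 lower_whisker = lw, upper_whisker = uw, n = n),
            class = "boxplot_summary")
}

#' @export
print.boxplot_summary <- function(x, ...) {
  cat(sprintf(
    "boxplot summary (n = %d): whiskers [%g, %g], quartiles [%g, %g], median %g\n",
    x$n, x$lower_whisker, x$upper_whisker, x$q1, x$q3, x$median))
  invisible(x)
}

#' SNP density per 1000 bp
#'
#' @param snp_sites Number of SNP sites (indels excluded).
#' @param mapped_length Mapped length in bp, > 0.
#' @return SNPs per 1000 bp.
#' @export
snp_density <- function(snp_sites, mapped_length) {
  if (any(mapped_length <= 0)) stop("'mapped_length' must be > 0")
  if (any(snp_sites < 0)) stop("'snp_sites' must be >= 0")
  1000 * snp_sites / mapped_length
}

#' Second-round absence screen
#'
#' A locus whose mean per-site depth after the second mapping round is below
#' 10 is regarded as absent from the sample (strict inequality).
#'
#' @param per_site_depth Non-empty numeric vector of per-site depths.
#' @return `"absent"` or `"retained"`.
#' @export
screen_absent_round2 <- function(per_site_depth) {
  if (length(per_site_depth) == 0) stop("depth vector must be non-empty")
  if (mean(per_site_depth) < 10) "absent" else "retained"
}

#' Third-round exclusion screen
#'
#' Applies the post-third-mapping filters: a gene is possibly absent if its
#' mean depth is below half the lower whisker of the species' gene-depth
#' boxplot, or too short if its mapped length is below 750 bp; a neutral
#' reference is excluded if shorter than 1000 bp; an autosomal neutral
#' reference is excluded as potentially duplicated if its mean depth
#' exceeds 1.5 times the upper whisker of the NR-A depth boxplot. All
#' comparisons are strict.
#'
#' @param records Data frame with columns `locus_id`, `kind` (`"gene"`,
#'   `"NR-A"`, `"NR-X"`), `mapped_length`, `mean_depth`.
#' @param gene_depth_boxplot,nr_a_depth_boxplot [boxplot_stats()] summaries
#'   of gene and NR-A mean depths for the species.
#' @return Data frame (`locus_id`, `reason`) of exclusions; zero rows when
#'   nothing is excluded.
#' @export
screen_round3 <- function(records, gene_depth_boxplot, nr_a_depth_boxplot) {
  if (!all(records$kind %in% c("gene", "NR-A", "NR-X")))
    stop("unknown record kind: ",
         paste(setdiff(records$kind, c("gene", "NR-A", "NR-X")), collapse = ", "))
  out <- data.frame(locus_id = character(), reason = character())
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    reason <- NULL
    if (r$kind == "gene") {
      if (r$mapped_length < 750) reason <- "short"
      else if (r$mean_depth < 0.5 * gene_depth_boxplot$lower_whisker)
        reason <- "possibly_absent"
    } else {
      if (r$mapped_length < 1000) reason <- "short"
      else if (r$kind == "NR-A" &&
               r$mean_depth > 1.5 * nr_a_depth_boxplot$upper_whisker)
        reason <- "duplicated"
    }
    if (!is.null(reason))
      out <- rbind(out, data.frame(locus_id = r$locus_id, reason = reason))
  }
  out
}

#' Flag duplication candidates from depth and SNP-density outliers
#'
#' A gene is a single locus only if both its mean depth and its SNP density
#' lie at or below the upper whiskers of the corresponding per-species
#' boxplots. Depth strictly above its whisker flags a duplication
#' candidate; SNP density alone above its whisker (depth not) routes the
#' gene toward the undecided high-SNP category.
#'
#' @param records Data frame with `locus_id`, `mean_depth`, `snp_density`
#'   (gene loci only, already screened).
#' @param depth_boxplot,snp_boxplot [boxplot_stats()] of the same records'
#'   mean depths and SNP densities.
#' @return `records` with an added `flag` column:
#'   `single_locus` / `candidate` / `high_snp_only`.
#' @export
flag_duplication_candidates <- function(records, depth_boxplot, snp_boxplot) {
  d_hi <- records$mean_depth > depth_boxplot$upper_whisker
  s_hi <- records$snp_density > snp_boxplot$upper_whisker
  records$flag <- ifelse(d_hi, "candidate",
                         ifelse(s_hi, "high_snp_only", "single_locus"))
  records
}

new_locus_call <- function(locus_id, call, category = NA_integer_,
                           round_decided = NA_integer_, children = "") {
  data.frame(locus_id = locus_id, call = call,
             category = as.integer(category),
             round_decided = as.integer(round_decided),
             children = children, stringsAsFactors = FALSE)
}

#' Resolve a flagged duplication candidate into a final locus call
#'
#' Reproduces the fourth/fifth mapping-round decision logic. If more than
#' the shared-read threshold (default 10%) of read-length windows are
#' identical between the two putative haplotype references, the reads are
#' not separable and the source sequence stays congregated (category 1,
#' round 4). Otherwise the locus is split into `-1`/`-2` children and the
#' children's depth and SNP density are re-examined against the species
#' whiskers: children within both whiskers give separated single-locus
#' genes (category 2); a child whose depth is again above the whisker is a
#' congregated category-3 gene at round 5; a child with only SNP density
#' above is displaced to category 4 (undecided).
#'
#' @param locus_id Candidate locus id.
#' @param H1,H2 The two putative haplotype reference sequences (character
#'   vectors); required when `shared_fraction` is `NA`.
#' @param shared_fraction Precomputed shared-window fraction, or `NA` to
#'   compute it from `H1`/`H2`.
#' @param post_split Data frame of round-4 child records (`locus_id`,
#'   `mean_depth`, `snp_sites`, `mapped_length`).
#' @param depth_boxplot,snp_boxplot Species-level whisker references.
#' @param shared_threshold Shared-window proportion above which reads are
#'   not separable (default 0.10).
#' @param read_len Window width for the shared fraction.
#' @return A data frame of locus calls: one row for the source locus and,
#'   when split, one per child.
#' @export
resolve_candidate <- function(locus_id, H1 = NULL, H2 = NULL,
                              shared_fraction = NA,
                              post_split = NULL,
                              depth_boxplot, snp_boxplot,
                              shared_threshold = 0.10, read_len = 150) {
  if (is.na(shared_fraction)) {
    if (is.null(H1) || is.null(H2))
      stop("candidate '", locus_id,
           "': haplotype sequences required to compute the shared fraction")
    shared_fraction <- shared_window_fraction(H1, H2, read_len)
  }
  if (shared_fraction > shared_threshold)
    return(new_locus_call(locus_id, "duplicated_congregated", 1L, 4L))

  if (is.null(post_split) || nrow(post_split) == 0)
    stop("candidate '", locus_id, "': post-split child records required")
  kids <- post_split
  kids$snp_density <- snp_density(kids$snp_sites, kids$mapped_length)
  calls <- list()
  for (i in seq_len(nrow(kids))) {
    k <- kids[i, ]
    d_hi <- k$mean_depth > depth_boxplot$upper_whisker
    s_hi <- k$snp_density > snp_boxplot$upper_whisker
    calls[[i]] <-
      if (d_hi) new_locus_call(k$locus_id, "duplicated_congregated", 3L, 5L)
      else if (s_hi) new_locus_call(k$locus_id, "high_snp_only", 4L, 5L)
      else new_locus_call(k$locus_id, "single_locus", round_decided = 4L)
  }
  calls <- do.call(rbind, calls)
  parent <- new_locus_call(locus_id, "split_single_locus", 2L, 4L,
                           children = paste(kids$locus_id, collapse = ","))
  rbind(parent, calls)
}

#' Run the full depth/SNP calling cascade on an emission
#'
#' Per species: screens absent loci (round 2), applies the round-3
#' exclusions, flags duplication candidates from depth and SNP-density
#' whiskers, and resolves every candidate through the shared-window and
#' split logic.
#'
#' @param emission A [emit_capture()] result, or a compatible list with
#'   `records`, `children`, `sequences`, `per_site`.
#' @param shared_threshold Shared-window separability threshold.
#' @return A list of class `locus_calls` with `calls` (per-locus call data
#'   frame with `species` column), `exclusions`, and `boxplots` (per
#'   species: gene depth, gene SNP density, NR-A depth summaries).
#' @export
call_loci <- function(emission, shared_threshold = 0.10) {
  records <- emission$records
  out_calls <- list()
  out_excl <- list()
  boxes <- list()
  for (sp in unique(records$species)) {
    rec <- records[records$species == sp, ]
    # round 2: absence by raw depth
    absent2 <- vapply(seq_len(nrow(rec)), function(i) {
      key <- paste(sp, rec$locus_id[i], sep = ":")
      dvec <- emission$per_site[[key]]
      if (is.null(dvec)) dvec <- rec$mean_depth[i]
      screen_absent_round2(dvec) == "absent"
    }, logical(1))
    for (id in rec$locus_id[absent2 & rec$kind == "gene"])
      out_calls[[length(out_calls) + 1L]] <-
        cbind(species = sp, new_locus_call(id, "absent", round_decided = 2L))
    out_excl[[length(out_excl) + 1L]] <-
      if (any(absent2)) data.frame(species = sp,
                                   locus_id = rec$locus_id[absent2],
                                   reason = "low_depth_round2")
      else NULL
    rec <- rec[!absent2, ]
    # round 3 screens
    gbox <- boxplot_stats(rec$mean_depth[rec$kind == "gene"])
    abox <- boxplot_stats(rec$mean_depth[rec$kind == "NR-A"])
    excl3 <- screen_round3(rec, gbox, abox)
    if (nrow(excl3)) {
      out_excl[[length(out_excl) + 1L]] <- cbind(species = sp, excl3)
      for (id in excl3$locus_id[excl3$locus_id %in%
                                rec$locus_id[rec$kind == "gene"]])
        out_calls[[length(out_calls) + 1L]] <-
          cbind(species = sp, new_locus_call(id, "absent", round_decided = 3L))
      rec <- rec[!rec$locus_id %in% excl3$locus_id, ]
    }
    genes <- rec[rec$kind == "gene", ]
    dbox <- boxplot_stats(genes$mean_depth)
    sbox <- boxplot_stats(genes$snp_density)
    boxes[[sp]] <- list(gene_depth = dbox, gene_snp = sbox, nr_a_depth = abox)
    genes <- flag_duplication_candidates(genes, dbox, sbox)
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      res <- switch(g$flag,
        single_locus = new_locus_call(g$locus_id, "single_locus",
                                      round_decided = 3L),
        high_snp_only = new_locus_call(g$locus_id, "high_snp_only", 4L, 4L),
        candidate = {
          key <- paste(sp, g$locus_id, sep = ":")
          sq <- emission$sequences[[key]]
          kids <- emission$children[
            emission$children$species == sp &
            emission$children$parent_locus == g$locus_id, , drop = FALSE]
          resolve_candidate(g$locus_id, H1 = sq$H1, H2 = sq$H2,
                            shared_fraction = g$shared_fraction,
                            post_split = kids,
                            depth_boxplot = dbox, snp_boxplot = sbox,
                            shared_threshold = shared_threshold)
        })
      out_calls[[length(out_calls) + 1L]] <- cbind(species = sp, res)
    }
  }
  calls <- do.call(rbind, out_calls)
  exclusions <- do.call(rbind, out_excl)
  if (is.null(exclusions))
    exclusions <- data.frame(species = character(), locus_id = character(),
                             reason = character())
  structure(list(calls = calls, exclusions = exclusions, boxplots = boxes),
            class = "locus_calls")
}
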