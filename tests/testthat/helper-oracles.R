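# Independent oracles and small fixture builders used across the suite.
# Each oracle is coded from first principles, separately from the package
# implementation it checks.

six_tip_tree <- function() {
  species_tree(ape::read.tree(
    text = "(((A:2,B:2):2,(C:2,D:2):2):2,(E:3,F:3):3):1;"))
}

four_tip_tree <- function() {
  species_tree(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1):1;"))
}

# --- brute-force median-inclusive boxplot oracle -------------------------
# quartiles: median of the lower/upper half, halves sharing the median
# element for odd n; whiskers: extreme data points inside the 1.5 IQR fences
oracle_boxplot <- function(v) {
  v <- sort(v)
  n <- length(v)
  mid <- function(u) {
    m <- length(u)
    if (m %% 2 == 1) u[(m + 1) / 2] else (u[m / 2] + u[m / 2 + 1]) / 2
  }
  if (n %% 2 == 1) {
    lo <- v[1:((n + 1) / 2)]
    hi <- v[((n + 1) / 2):n]
  } else {
    lo <- v[1:(n / 2)]
    hi <- v[(n / 2 + 1):n]
  }
  q1 <- mid(lo); q3 <- mid(hi); iqr <- q3 - q1
  inside <- v[v >= q1 - 1.5 * iqr & v <= q3 + 1.5 * iqr]
  list(q1 = q1, median = mid(v), q3 = q3, iqr = iqr,
       lower_whisker = min(inside), upper_whisker = max(inside))
}

# --- TN93 closed form from explicitly tabulated site patterns ------------
oracle_tn93 <- function(a, b) {
  keep <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  tab <- table(factor(a, levels = c("A", "C", "G", "T")),
               factor(b, levels = c("A", "C", "G", "T")))
  P1 <- (tab["A", "G"] + tab["G", "A"]) / n
  P2 <- (tab["C", "T"] + tab["T", "C"]) / n
  Q <- (n - sum(diag(tab))) / n - P1 - P2
  f <- (rowSums(tab) + colSums(tab)) / (2 * n)
  gA <- f["A"]; gC <- f["C"]; gG <- f["G"]; gT <- f["T"]
  gR <- gA + gG; gY <- gC + gT
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gC * gT / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY)
  unname(-k1 * log(1 - P1 / k1 - Q / (2 * gR)) -
          k2 * log(1 - P2 / k2 - Q / (2 * gY)) -
          k3 * log(1 - Q / (2 * gR * gY)))
}

# --- hydropathy sliding-window oracle (explicit state machine) -----------
oracle_tm_count <- function(aa, window = 19, threshold = 1.6, min_gap = 3) {
  kd <- bitterfam:::KD_SCALE[aa]
  kd[is.na(kd)] <- 0
  if (length(kd) < window) return(0L)
  hits <- logical(length(kd) - window + 1)
  for (i in seq_along(hits)) hits[i] <- sum(kd[i:(i + window - 1)]) / window > threshold
  segs <- 0L; in_seg <- FALSE; gap <- 0L
  for (h in hits) {
    if (h) {
      if (!in_seg && (segs == 0L || gap >= min_gap)) segs <- segs + 1L
      else if (!in_seg && gap < min_gap) NULL  # merged into previous
      in_seg <- TRUE; gap <- 0L
    } else {
      if (in_seg) gap <- 1L else gap <- gap + 1L
      in_seg <- FALSE
    }
  }
  segs
}

# --- exhaustive Dollo event minimizer on a 4-tip tree --------------------
# minimal births+losses explaining a presence pattern for one gene,
# enumerating every (birth branch, loss branch subset)
oracle_min_events <- function(tree, present) {
  phy <- tree$phy
  tips <- phy$tip.label
  nodes <- tree$branch_ids$node
  best <- Inf
  for (b_node in nodes) {
    scope <- tips_below(tree, b_node)
    if (!all(present %in% scope)) next
    cand <- nodes[vapply(nodes, function(n)
      all(tips_below(tree, n) %in% scope), logical(1))]
    for (k in 0:length(cand)) {
      combs <- utils::combn(cand, k, simplify = FALSE)
      if (k == 0) combs <- list(integer(0))
      for (losses in combs) {
        lost_tips <- unique(unlist(lapply(losses, tips_below, tree = tree)))
        alive <- setdiff(scope, lost_tips)
        if (setequal(alive, present)) best <- min(best, 1 + length(losses))
      }
    }
  }
  best
}

# --- synthetic single-species repertoire with an optional duplicate ------
# n_single single-copy genes plus, if divergence is not NA, one duplicated
# pair (locus G01) whose copies differ at ~divergence of their sites
synth_repertoire <- function(seed, n_single = 30, divergence = NA,
                             cfg = NULL) {
  set.seed(seed)
  if (is.null(cfg)) cfg <- simulation_config(seed = seed)
  L <- cfg$coding_len + 2 * cfg$flank_len
  template <- c(sample(c("A", "C", "G", "T"), cfg$flank_len, TRUE),
                gene_template(cfg$coding_len),
                sample(c("A", "C", "G", "T"), cfg$flank_len, TRUE))
  ids <- sprintf("G%02d", seq_len(n_single))
  genes <- data.frame(gene_id = ids, parent = NA_character_,
                      state = "intact", tag = NA_character_, born = FALSE)
  H1 <- H2 <- list()
  for (id in ids) {
    s <- bitterfam:::mutate_sites(template, rpois(1, 0.01 * L), cfg, TRUE)
    h2 <- s
    for (p in sample.int(L, rpois(1, cfg$het_rate * L)))
      h2[p] <- bitterfam:::draw_alt_base(h2[p], cfg)
    H1[[id]] <- s
    H2[[id]] <- h2
  }
  if (!is.na(divergence)) {
    dup_id <- "G01.d001"
    genes <- rbind(genes, data.frame(gene_id = dup_id, parent = "G01",
                                     state = "intact", tag = NA, born = TRUE))
    s <- H1[["G01"]]
    for (p in sample.int(L, round(divergence * L)))
      s[p] <- bitterfam:::draw_alt_base(s[p], cfg)
    H1[[dup_id]] <- s
    H2[[dup_id]] <- s
  }
  list(S = list(species = "S", genes = genes, H1 = H1, H2 = H2))
}
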