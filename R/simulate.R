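#' Configuration for the gene-family capture simulator
#'
#' Bundles and validates every tunable of the forward simulator: the
#' birth/disruption/loss/conversion process on the species tree, the
#' substitution model, the diploid sampling layer (heterozygous sites,
#' segregating pseudogenes, unphased sites) and the capture-style depth
#' emission.
#'
#' Rates are per gene (or per duplicate pair for `conversion_rate`) per unit
#' branch length of the species tree. Depth is parameterized for a diploid
#' single-copy autosomal locus; a congregated paralog pair is emitted at
#' twice that expectation.
#'
#' @param birth_rate Duplications per gene per time unit.
#' @param disruption_rate Disruptive mutations per intact gene per time unit.
#' @param loss_rate Whole-gene deletions per gene per time unit.
#' @param conversion_rate Homogenization events per intact duplicate pair per
#'   time unit.
#' @param root_repertoire_size Number of single-copy genes at the root.
#' @param subst_rate Substitutions per site per time unit on the species
#'   tree (applied to flanks and, scaled by `gene_rate_multiplier`, to intact
#'   coding regions).
#' @param kappa1,kappa2 Purine (A/G) and pyrimidine (C/T) transition weights
#'   of the TN93-style substitution kernel, relative to a transversion
#'   weight of 1.
#' @param gene_rate_multiplier Factor (< 1 for purifying constraint) applied
#'   to the substitution and heterozygosity rates inside intact coding
#'   regions. Disrupted copies evolve at the neutral rate.
#' @param het_rate Expected heterozygous sites per site in the sampled
#'   diploid individual (neutral rate; coding regions of intact genes are
#'   scaled by `gene_rate_multiplier`).
#' @param disruption_mix Probability that a disruptive mutation is a
#'   premature stop codon; otherwise it is a 1-bp frameshift deletion.
#' @param seg_pseudo_prob Probability that a disruption drawn on a terminal
#'   branch is heterozygous in the sampled individual (a segregating
#'   pseudogene) rather than fixed.
#' @param unphased_prob Probability that a heterozygous site is emitted
#'   unphased (as an IUPAC degenerate code in both haplotypes).
#' @param depth_mean Expected per-site depth of a diploid single-copy
#'   autosomal locus.
#' @param depth_dispersion Negative-binomial size parameter of per-site
#'   depth (smaller = more overdispersed).
#' @param sigma_locus Standard deviation (log scale) of the per-locus
#'   capture-efficiency effect; the effect is normalized to mean 1.
#' @param read_len Read length in nucleotides, the window used for the
#'   shared-window fraction between paralog haplotypes.
#' @param coding_len,flank_len Lengths (nt) of the coding region and of each
#'   flank of a simulated gene.
#' @param root_gene_divergence Expected per-site divergence among root
#'   repertoire genes.
#' @param emit_sequences If `FALSE`, skip all sequence evolution (histories
#'   and states only; depth emission is then unavailable).
#' @param seed Integer seed; mandatory, no implicit entropy.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(birth_rate = 0.01,
                              disruption_rate = 0.02,
                              loss_rate = 0.01,
                              conversion_rate = 0.1,
                              root_repertoire_size = 32,
                              subst_rate = 0.002,
                              kappa1 = 4, kappa2 = 4,
                              gene_rate_multiplier = 0.4,
                              het_rate = 0.004,
                              disruption_mix = 0.5,
                              seg_pseudo_prob = 0.3,
                              unphased_prob = 0.1,
                              depth_mean = 1000,
                              depth_dispersion = 10,
                              sigma_locus = 0.1,
                              read_len = 150,
                              coding_len = 900,
                              flank_len = 100,
                              root_gene_divergence = 0.02,
                              emit_sequences = TRUE,
                              seed) {
  if (missing(seed) || is.null(seed))
    stop("'seed' is mandatory: the simulator has no implicit entropy")
  seed <- as.integer(seed)
  if (is.na(seed) || abs(seed) > 2^31 - 100)
    stop("'seed' must be an integer below 2^31")
  rates <- c(birth_rate = birth_rate, disruption_rate = disruption_rate,
             loss_rate = loss_rate, conversion_rate = conversion_rate,
             subst_rate = subst_rate, het_rate = het_rate)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and >= 0")
  probs <- c(disruption_mix = disruption_mix,
             seg_pseudo_prob = seg_pseudo_prob, unphased_prob = unphased_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (depth_mean <= 0) stop("'depth_mean' must be > 0")
  if (depth_dispersion <= 0) stop("'depth_dispersion' must be > 0")
  if (coding_len %% 3 != 0) stop("'coding_len' must be a codon multiple")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Template coding sequence of a simulated receptor gene
#'
#' Returns the deterministic coding sequence (as a character vector of
#' single bases) used as the common ancestor of all simulated genes. The
#' protein it encodes carries seven strongly hydrophobic stretches separated
#' by charged linkers, so an unmutated copy passes both the maximal-ORF and
#' the seven-transmembrane hydropathy test. The hydrophilic linkers contain
#' stop codons in both shifted reading frames, so a frameshift anywhere in
#' the coding region truncates the open reading frame within roughly one
#' linker distance.
#'
#' @param coding_len Coding length in nt (codon multiple, >= 750 + margin).
#' @return Character vector of `coding_len` single characters.
#' @export
gene_template <- function(coding_len = 900) {
  n_codons <- coding_len / 3
  # +1/+2-frame stops live in "CTA AAA" and "AAT AAA"
  linker <- c("GAA", "AAA", "CTA", "AAA", "AAT", "AAA", "GAA", "CAA")
  block <- rep(c("CTG", "ATT", "GTT", "TTT", "CTC", "ATC", "GTC", "TTC"),
               length.out = 23)
  codons <- c("ATG", linker)
  for (i in 1:7) codons <- c(codons, block, linker)
  pad <- rep(c("AAA", "GAA"), length.out = n_codons - length(codons) - 1)
  codons <- c(codons, pad, "TAA")
  stopifnot(length(codons) == n_codons)
  unlist(strsplit(codons, ""), use.names = FALSE)
}

# positions (1-based, in the full flank+coding+flank coordinate system)
coding_range <- function(cfg) (cfg$flank_len + 1):(cfg$flank_len + cfg$coding_len)

# does substituting newbase at pos break the frame-0 reading of the coding
# region (create a stop, or destroy the start codon)?
would_disrupt_frame <- function(seq, pos, newbase, cfg) {
  cstart <- cfg$flank_len + 1L
  cend <- cfg$flank_len + cfg$coding_len
  if (pos < cstart || pos > cend) return(FALSE)
  codon_idx <- (pos - cstart) %/% 3L
  cpos <- cstart + 3L * codon_idx
  codon <- seq[cpos:(cpos + 2L)]
  codon[pos - cpos + 1L] <- newbase
  if (any(codon == "-")) return(FALSE)
  codon <- paste(codon, collapse = "")
  if (codon_idx == 0L && codon != "ATG") return(TRUE)
  # keep the native terminal stop; reject new internal stops
  if (codon %in% STOP_CODONS && cpos + 2L != cend) return(TRUE)
  FALSE
}

# TN93-like substitution kernel: draw a different base, transitions weighted
draw_alt_base <- function(base, cfg) {
  w <- switch(base,
    A = c(C = 1, G = cfg$kappa1, T = 1),
    G = c(A = cfg$kappa1, C = 1, T = 1),
    C = c(A = 1, G = 1, T = cfg$kappa2),
    T = c(A = 1, C = cfg$kappa2, G = 1),
    return(base))
  sample(names(w), 1L, prob = w)
}

# per-site sampling weights: flanks 1, intact coding scaled, gaps 0
site_weights <- function(seq, cfg, protected) {
  w <- rep(1, length(seq))
  if (protected) w[coding_range(cfg)] <- cfg$gene_rate_multiplier
  w[seq == "-"] <- 0
  w
}

# evolve a sequence for time t; protected sequences keep a readable frame
evolve_seq <- function(seq, t, cfg, protected) {
  if (t <= 0 || cfg$subst_rate == 0) return(seq)
  w <- site_weights(seq, cfg, protected)
  n <- stats::rpois(1, cfg$subst_rate * t * sum(w))
  if (n == 0) return(seq)
  for (i in seq_len(n)) {
    for (try in 1:25) {
      pos <- sample.int(length(seq), 1L, prob = w)
      alt <- draw_alt_base(seq[pos], cfg)
      if (!protected || !would_disrupt_frame(seq, pos, alt, cfg)) {
        seq[pos] <- alt
        break
      }
    }
  }
  seq
}

# choose a disruptive mutation; returns list(tag, apply = function(seq) seq)
draw_disruption <- function(cfg) {
  if (stats::runif(1) < cfg$disruption_mix) {
    # premature stop placed so both flanking ORF fragments stay < 750 bp
    lo <- ceiling((cfg$coding_len - 750) / 3) + 2L
    hi <- floor(750 / 3) - 1L
    codon <- sample(seq.int(lo, hi), 1L)
    pos <- cfg$flank_len + 3L * (codon - 1L) + 1L
    list(tag = sprintf("stop@codon%d", codon),
         apply = function(s) { s[pos:(pos + 2L)] <- c("T", "A", "A"); s })
  } else {
    off <- sample(150:600, 1L)
    pos <- cfg$flank_len + off
    list(tag = sprintf("del@%d", off),
         apply = function(s) { s[pos] <- "-"; s })
  }
}

empty_history <- function() {
  data.frame(branch_id = integer(), event = character(),
             gene_id = character(), parent_gene_id = character(),
             detail = character(), intact_before = logical(),
             segregating = logical(), stringsAsFactors = FALSE)
}

#' Simulate a gene-family history along a species tree
#'
#' Runs a Gillespie birth/disruption/loss/conversion process independently
#' along every branch of `tree`, evolving sequences between events, and
#' samples one diploid individual per tip. Gene births duplicate an existing
#' copy in place; conversions overwrite one intact member of a duplicate
#' pair with its partner's sequence; losses delete the copy from all
#' descendants; disruptions insert a premature stop or a 1-bp frameshift,
#' and on terminal branches become segregating (heterozygous) with
#' probability `seg_pseudo_prob`.
#'
#' @param tree A [species_tree()].
#' @param cfg A [simulation_config()].
#' @return A list of class `sim_history` with elements
#'   `history` (event data frame: branch_id, event, gene_id,
#'   parent_gene_id, detail, intact_before, segregating),
#'   `repertoires` (per-tip list: `genes` data frame plus `H1`/`H2` allele
#'   sequence lists), `tree` and `cfg`.
#' @examples
#' tr <- species_tree(ape::read.tree(text = "((A:1,B:1):1,C:2):1;"))
#' sim <- simulate_history(tr, simulation_config(seed = 1,
#'   root_repertoire_size = 4, emit_sequences = FALSE))
#' sim$repertoires$A$genes
#' @export
simulate_history <- function(tree, cfg) {
  stopifnot(inherits(tree, "species_tree"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  root <- ntip + 1L

  template <- gene_template(cfg$coding_len)
  L <- cfg$coding_len + 2L * cfg$flank_len

  make_root_gene <- function(id) {
    seq <- c(sample(c("A", "C", "G", "T"), cfg$flank_len, replace = TRUE),
             template,
             sample(c("A", "C", "G", "T"), cfg$flank_len, replace = TRUE))
    n_div <- stats::rpois(1, cfg$root_gene_divergence * L)
    seq <- mutate_sites(seq, n_div, cfg, protected = TRUE)
    list(gene_id = id, parent = NA_character_, state = "intact",
         tag = NA_character_, born = FALSE, seq = seq)
  }

  n0 <- cfg$root_repertoire_size
  ids <- sprintf("G%02d", seq_len(n0))
  state0 <- lapply(ids, function(id) {
    if (cfg$emit_sequences) make_root_gene(id)
    else list(gene_id = id, parent = NA_character_, state = "intact",
              tag = NA_character_, born = FALSE, seq = NULL)
  })
  names(state0) <- ids

  history <- empty_history()
  repertoires <- vector("list", ntip)
  names(repertoires) <- phy$tip.label
  counter <- 0L

  recurse <- function(node, state) {
    t_branch <- branch_length_into(tree, node)
    is_tip <- node <= ntip
    res <- run_branch(state, t_branch, branch_of_node(tree, node),
                      is_tip, cfg, counter)
    counter <<- res$counter
    history <<- rbind(history, res$events)
    state <- res$state
    if (is_tip) {
      repertoires[[phy$tip.label[node]]] <<-
        sample_individual(state, phy$tip.label[node], cfg)
    } else {
      for (kid in node_children(tree, node)) recurse(kid, state)
    }
  }
  recurse(root, state0)

  structure(list(history = history, repertoires = repertoires,
                 tree = tree, cfg = cfg), class = "sim_history")
}

# apply n substitutions (used for root-gene divergence)
mutate_sites <- function(seq, n, cfg, protected) {
  if (n == 0) return(seq)
  w <- site_weights(seq, cfg, protected)
  for (i in seq_len(n)) {
    for (try in 1:25) {
      pos <- sample.int(length(seq), 1L, prob = w)
      alt <- draw_alt_base(seq[pos], cfg)
      if (!protected || !would_disrupt_frame(seq, pos, alt, cfg)) {
        seq[pos] <- alt
        break
      }
    }
  }
  seq
}

# Gillespie walk along one branch
run_branch <- function(state, t_branch, branch_id, is_tip, cfg, counter) {
  events <- empty_history()
  t <- 0
  repeat {
    genes <- names(state)
    n <- length(genes)
    intact <- genes[vapply(state, function(g) g$state == "intact", logical(1))]
    pairs <- intact_pairs(state)
    r_birth <- cfg$birth_rate * n
    r_disr <- cfg$disruption_rate * length(intact)
    r_loss <- cfg$loss_rate * n
    r_conv <- cfg$conversion_rate * nrow(pairs)
    r_tot <- r_birth + r_disr + r_loss + r_conv
    if (r_tot == 0 || n == 0) {
      state <- evolve_all(state, t_branch - t, cfg)
      break
    }
    dt <- stats::rexp(1, r_tot)
    if (t + dt > t_branch) {
      state <- evolve_all(state, t_branch - t, cfg)
      break
    }
    state <- evolve_all(state, dt, cfg)
    t <- t + dt
    kind <- sample(c("birth", "disruption", "loss", "conversion"), 1L,
                   prob = c(r_birth, r_disr, r_loss, r_conv))
    if (kind == "birth") {
      src <- sample(genes, 1L)
      counter <- counter + 1L
      newid <- sprintf("%s.d%03d", src, counter)
      g <- state[[src]]
      state[[newid]] <- list(gene_id = newid, parent = src, state = g$state,
                             tag = g$tag, born = TRUE, seq = g$seq,
                             seg_apply = g$seg_apply)
      events <- rbind(events, data.frame(
        branch_id = branch_id, event = "birth", gene_id = newid,
        parent_gene_id = src, detail = NA_character_,
        intact_before = g$state %in% c("intact", "segregating"),
        segregating = FALSE))
    } else if (kind == "disruption") {
      victim <- sample(intact, 1L)
      mut <- draw_disruption(cfg)
      seg <- is_tip && stats::runif(1) < cfg$seg_pseudo_prob
      if (seg) {
        state[[victim]]$state <- "segregating"
        state[[victim]]$tag <- mut$tag
        state[[victim]]$seg_apply <- mut$apply
      } else {
        state[[victim]]$state <- "disrupted"
        state[[victim]]$tag <- mut$tag
        if (!is.null(state[[victim]]$seq))
          state[[victim]]$seq <- mut$apply(state[[victim]]$seq)
      }
      events <- rbind(events, data.frame(
        branch_id = branch_id, event = "disruption", gene_id = victim,
        parent_gene_id = NA_character_, detail = mut$tag,
        intact_before = TRUE, segregating = seg))
    } else if (kind == "loss") {
      victim <- sample(genes, 1L)
      was_intactish <- state[[victim]]$state %in% c("intact", "segregating")
      events <- rbind(events, data.frame(
        branch_id = branch_id, event = "loss", gene_id = victim,
        parent_gene_id = NA_character_, detail = NA_character_,
        intact_before = was_intactish, segregating = FALSE))
      state[[victim]] <- NULL
    } else { # conversion: overwrite one intact duplicate with its partner
      k <- sample.int(nrow(pairs), 1L)
      pair <- unlist(pairs[k, c("a", "b")])
      if (stats::runif(1) < 0.5) pair <- rev(pair)
      if (!is.null(state[[pair[1]]]$seq))
        state[[pair[2]]]$seq <- state[[pair[1]]]$seq
      events <- rbind(events, data.frame(
        branch_id = branch_id, event = "conversion", gene_id = pair[2],
        parent_gene_id = pair[1], detail = NA_character_,
        intact_before = TRUE, segregating = FALSE))
    }
  }
  list(state = state, events = events, counter = counter)
}

# parent/child duplicate pairs with both members present and intact
intact_pairs <- function(state) {
  out <- data.frame(a = character(), b = character())
  for (g in state) {
    if (isTRUE(g$born) && !is.na(g$parent) && !is.null(state[[g$parent]])) {
      if (g$state == "intact" && state[[g$parent]]$state == "intact")
        out <- rbind(out, data.frame(a = g$parent, b = g$gene_id))
    }
  }
  out
}

evolve_all <- function(state, t, cfg) {
  if (!cfg$emit_sequences || t <= 0) return(state)
  for (id in names(state)) {
    prot <- state[[id]]$state %in% c("intact", "segregating")
    state[[id]]$seq <- evolve_seq(state[[id]]$seq, t, cfg, protected = prot)
  }
  state
}

# materialize the diploid individual at a tip
sample_individual <- function(state, species, cfg) {
  genes <- data.frame(
    gene_id = names(state),
    parent = vapply(state, function(g) g$parent, character(1)),
    state = vapply(state, function(g) g$state, character(1)),
    tag = vapply(state, function(g) g$tag, character(1)),
    born = vapply(state, function(g) isTRUE(g$born), logical(1)),
    row.names = NULL)
  H1 <- H2 <- NULL
  if (cfg$emit_sequences) {
    H1 <- H2 <- vector("list", nrow(genes))
    names(H1) <- names(H2) <- genes$gene_id
    for (id in genes$gene_id) {
      g <- state[[id]]
      prot <- g$state %in% c("intact", "segregating")
      w <- site_weights(g$seq, cfg, protected = prot)
      n_het <- stats::rpois(1, cfg$het_rate * sum(w))
      h1 <- h2 <- g$seq
      if (n_het > 0) {
        for (i in seq_len(n_het)) {
          for (try in 1:25) {
            pos <- sample.int(length(g$seq), 1L, prob = w)
            alt <- draw_alt_base(g$seq[pos], cfg)
            if (!prot || !would_disrupt_frame(g$seq, pos, alt, cfg)) {
              if (stats::runif(1) < 0.5) h1[pos] <- alt else h2[pos] <- alt
              break
            }
          }
        }
      }
      if (g$state == "segregating") h2 <- g$seg_apply(h2)
      H1[[id]] <- h1
      H2[[id]] <- h2
    }
  }
  list(species = species, genes = genes, H1 = H1, H2 = H2)
}

IUPAC_CODE <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

# emit a haplotype pair with some heterozygous sites left unphased
unphase_pair <- function(h1, h2, cfg) {
  het <- which(h1 != h2 & h1 != "-" & h2 != "-")
  if (length(het)) {
    flip <- het[stats::runif(length(het)) < cfg$unphased_prob]
    for (pos in flip) {
      key <- paste(sort(c(h1[pos], h2[pos])), collapse = "")
      code <- IUPAC_CODE[[key]]
      h1[pos] <- code
      h2[pos] <- code
    }
  }
  list(H1 = h1, H2 = h2)
}

#' Fraction of read-length windows identical between two haplotypes
#'
#' Operationalizes the shared-read proportion between two putative paralog
#' references: the fraction of consecutive non-overlapping `read_len`-wide
#' windows in which the two sequences are identical, i.e. windows whose
#' reads could map to either reference.
#'
#' @param a,b Equal-length character vectors (single bases).
#' @param read_len Window width in nt.
#' @return A value in `[0, 1]`.
#' @export
shared_window_fraction <- function(a, b, read_len = 150) {
  stopifnot(length(a) == length(b))
  n_win <- length(a) %/% read_len
  if (n_win == 0) return(as.numeric(all(a == b)))
  same <- vapply(seq_len(n_win), function(i) {
    idx <- ((i - 1) * read_len + 1):(i * read_len)
    all(a[idx] == b[idx])
  }, logical(1))
  mean(same)
}

#' Emit capture-style depth and SNP summaries for simulated repertoires
#'
#' Converts the diploid repertoires of a [simulate_history()] run into the
#' per-locus summary records that the mapping pipeline would produce:
#' per-site depth drawn from an overdispersed negative-binomial with mean
#' proportional to copy number, heterozygous-site counts, and -- for
#' paralog pairs born on the tree, which a capture design probes through a
#' single ancestral reference -- a single congregated locus with summed
#' depth, the union of SNP sites (heterozygous plus inter-paralog), the two
#' paralog consensus sequences as H1/H2, and their shared-window fraction.
#' Child records (suffix `-1`/`-2`) carrying each copy's own depth and SNP
#' count are attached for downstream separation. Autosomal and X neutral
#' reference loci are appended via [emit_neutral_reference_set()].
#'
#' @param sim A `sim_history` (or its `repertoires` element).
#' @param cfg The [simulation_config()] used for the simulation.
#' @param sex Named character vector, one of `"male"`/`"female"` per
#'   species; unnamed scalar recycles to all species.
#' @param n_nr_a,n_nr_x Numbers of autosomal and X neutral reference loci.
#' @return A list of class `capture_emission`: `records` (one row per
#'   locus), `children` (post-split records for congregated loci),
#'   `sequences` (per-locus H1/H2, heterozygous sites partially unphased to
#'   IUPAC codes) and `per_site` (depth vectors).
#' @export
emit_capture <- function(sim, cfg, sex = "male", n_nr_a = 83, n_nr_x = 3) {
  reps <- if (inherits(sim, "sim_history")) sim$repertoires else sim
  if (!cfg$emit_sequences)
    stop("emission requires sequences; rerun with emit_sequences = TRUE")
  species <- names(reps)
  if (is.null(names(sex)) && length(sex) == 1L)
    sex <- stats::setNames(rep(sex, length(species)), species)
  if (!all(species %in% names(sex)))
    stop("'sex' must name every species")
  if (!all(sex %in% c("male", "female")))
    stop("unknown sex label: ", paste(setdiff(sex, c("male", "female")),
                                      collapse = ", "))
  set.seed(cfg$seed + 1L)

  rec_list <- list()
  child_list <- list()
  seqs <- list()
  depth <- list()

  for (sp in species) {
    rep_ <- reps[[sp]]
    groups <- locus_groups(rep_$genes)
    for (grp in groups) {
      locus <- grp[1]
      n_copy <- length(grp)
      h1_full <- rep_$H1[[grp[1]]]
      eff <- locus_effect(cfg)
      dvec <- rnbinom_depth(length(h1_full), cfg$depth_mean * eff, cfg)
      if (n_copy > 1)
        for (g in grp[-1])
          dvec <- dvec + rnbinom_depth(length(h1_full),
                                       cfg$depth_mean * eff, cfg)
      if (n_copy == 1L) {
        pair <- unphase_pair(rep_$H1[[locus]], rep_$H2[[locus]], cfg)
        snp <- n_het_sites(rep_$H1[[locus]], rep_$H2[[locus]])
        shared <- NA_real_
      } else {
        # congregated: the two paralog consensus sequences act as H1/H2
        a <- rep_$H1[[grp[1]]]
        b <- rep_$H1[[grp[2]]]
        pair <- list(H1 = a, H2 = b)
        snp <- length(unique(c(
          which(a != b & a != "-" & b != "-"),
          unlist(lapply(grp, function(g)
            which(rep_$H1[[g]] != rep_$H2[[g]] &
                  rep_$H1[[g]] != "-" & rep_$H2[[g]] != "-"))))))
        shared <- shared_window_fraction(a, b, cfg$read_len)
        for (i in seq_len(min(n_copy, 2L))) {
          g <- grp[i]
          eff_c <- locus_effect(cfg)
          dvec_c <- rnbinom_depth(length(h1_full), cfg$depth_mean * eff_c, cfg)
          child_list[[length(child_list) + 1L]] <- data.frame(
            species = sp, parent_locus = locus,
            locus_id = paste0(locus, "-", i),
            mapped_length = sum(rep_$H1[[g]] != "-"),
            mean_depth = mean(dvec_c),
            snp_sites = n_het_sites(rep_$H1[[g]], rep_$H2[[g]]))
        }
      }
      len <- sum(pair$H1 != "-" | pair$H2 != "-")
      key <- paste(sp, locus, sep = ":")
      seqs[[key]] <- pair
      depth[[key]] <- dvec
      rec_list[[length(rec_list) + 1L]] <- data.frame(
        species = sp, locus_id = locus, kind = "gene",
        mapped_length = len, mean_depth = mean(dvec), snp_sites = snp,
        shared_fraction = shared, copy_number = 2L * n_copy,
        n_genes = n_copy)
    }
    nr <- emit_neutral_reference_set(n_nr_a, n_nr_x, lengths = NULL,
                                     cfg = cfg, sex = sex[[sp]],
                                     species = sp, reseed = FALSE)
    nr$records$snp_density <- NULL
    rec_list[[length(rec_list) + 1L]] <- nr$records
    depth <- c(depth, nr$per_site)
  }
  records <- do.call(rbind, rec_list)
  records$snp_density <- 1000 * records$snp_sites / records$mapped_length
  children <- if (length(child_list)) do.call(rbind, child_list) else
    data.frame(species = character(), parent_locus = character(),
               locus_id = character(), mapped_length = integer(),
               mean_depth = numeric(), snp_sites = integer())
  structure(list(records = records, children = children,
                 sequences = seqs, per_site = depth),
            class = "capture_emission")
}

# loci sharing a capture reference: a gene born on the tree congregates with
# its present ancestor chain; root genes anchor their own locus
locus_groups <- function(genes) {
  anchor <- vapply(genes$gene_id, function(id) {
    cur <- id
    repeat {
      i <- match(cur, genes$gene_id)
      par <- genes$parent[i]
      if (!genes$born[i] || is.na(par) || !(par %in% genes$gene_id))
        return(cur)
      cur <- par
    }
  }, character(1))
  split(genes$gene_id, anchor)
}

locus_effect <- function(cfg) {
  stats::rlnorm(1, meanlog = -cfg$sigma_locus^2 / 2, sdlog = cfg$sigma_locus)
}

rnbinom_depth <- function(n, mu, cfg) {
  stats::rnbinom(n, mu = mu, size = cfg$depth_dispersion)
}

n_het_sites <- function(h1, h2) sum(h1 != h2 & h1 != "-" & h2 != "-")

#' Emit single-copy neutral reference loci
#'
#' Neutral references are single-locus non-coding regions used to calibrate
#' depth (ploidy) and neutral SNP density. Autosomal loci (`NR-A`) are
#' emitted at the diploid expectation; X-chromosomal loci (`NR-X`) at half
#' of it for males. SNP counts are drawn at the full neutral rate, the
#' highest in the simulator.
#'
#' @inheritParams emit_capture
#' @param n_autosomal,n_x Locus counts (defaults follow a realized capture
#'   probe design of 83 autosomal and 3 X regions).
#' @param lengths Optional vector of locus lengths (bp, >= 1000); drawn
#'   uniformly in 1000-2000 bp when `NULL`.
#' @param sex `"male"` or `"female"`.
#' @param species Species label written into the records.
#' @param reseed Internal; set `FALSE` when called with the RNG already
#'   positioned.
#' @return A list with `records` and `per_site`, the same shapes as the
#'   corresponding [emit_capture()] slots.
#' @export
emit_neutral_reference_set <- function(n_autosomal = 83, n_x = 3,
                                       lengths = NULL, cfg, sex = "male",
                                       species = "sample", reseed = TRUE) {
  if (!sex %in% c("male", "female")) stop("unknown sex label: ", sex)
  if (n_autosomal < 0 || n_x < 0) stop("locus counts must be >= 0")
  if (reseed) set.seed(cfg$seed + 2L)
  n <- n_autosomal + n_x
  if (is.null(lengths)) lengths <- sample(1000:2000, n, replace = TRUE)
  if (length(lengths) != n) stop("'lengths' must have one entry per locus")
  if (any(lengths < 1000)) stop("neutral reference loci must be >= 1000 bp")
  kind <- c(rep("NR-A", n_autosomal), rep("NR-X", n_x))
  ids <- c(sprintf("NRA%03d", seq_len(n_autosomal)),
           if (n_x > 0) sprintf("NRX%03d", seq_len(n_x)))
  per_site <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    scale <- if (kind[i] == "NR-X" && sex == "male") 0.5 else 1
    eff <- locus_effect(cfg)
    dvec <- rnbinom_depth(lengths[i], cfg$depth_mean * scale * eff, cfg)
    snp <- stats::rpois(1, cfg$het_rate * lengths[i] *
                          (if (kind[i] == "NR-X" && sex == "male") 0 else 1))
    per_site[[i]] <- dvec
    rows[[i]] <- data.frame(
      species = species, locus_id = ids[i], kind = kind[i],
      mapped_length = lengths[i], mean_depth = mean(dvec),
      snp_sites = snp, shared_fraction = NA_real_,
      copy_number = if (scale == 0.5) 1L else 2L, n_genes = 1L)
  }
  names(per_site) <- paste(species, ids, sep = ":")
  records <- do.call(rbind, rows)
  records$snp_density <- 1000 * records$snp_sites / records$mapped_length
  list(records = records, per_site = per_site)
}
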