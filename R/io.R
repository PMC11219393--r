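#' Read and write FASTA preserving IUPAC codes
#'
#' Thin wrappers around seqinr keeping sequences as uppercase single-base
#' character vectors, with degenerate IUPAC codes and alignment gaps
#' passed through unchanged.
#'
#' @param path File path.
#' @return `read_fasta()`: named list of character vectors.
#' @export
read_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "DNA", forceDNAtolower = FALSE,
                             set.attributes = FALSE)
  lapply(recs, toupper)
}

#' @rdname read_fasta
#' @param seqs Named list of sequences (strings or base vectors).
#' @param header_note Optional comment placed in the first header line
#'   (e.g. the seed used to generate the file).
#' @export
write_fasta <- function(seqs, path, header_note = NULL) {
  seqs <- lapply(seqs, as_base_vector)
  nms <- names(seqs)
  if (!is.null(header_note)) nms[1] <- paste(nms[1], header_note)
  seqinr::write.fasta(seqs, names = nms, file.out = path, nbchar = 70)
  invisible(path)
}

#' Read and write Newick trees
#'
#' @param path File path.
#' @return `read_newick()`: an [ape::phylo].
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @param phy An [ape::phylo].
#' @export
write_newick <- function(phy, path) {
  ape::write.tree(phy, file = path, digits = 6)
  invisible(path)
}

#' Read a headered TSV, enforcing required columns
#'
#' Lines starting with `#` are treated as comments (output files carry the
#' generating seed there).
#'
#' @param path File path.
#' @param required Character vector of required column names.
#' @return Data frame.
#' @export
read_tsv_checked <- function(path, required = character(0)) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' @rdname read_tsv_checked
#' @param df Data frame to write.
#' @param header_note Optional `#` comment line (seed provenance).
#' @export
write_tsv <- function(df, path, header_note = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_note)) writeLines(paste0("# ", header_note), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-site depth as BED-like intervals
#'
#' Coordinates are 0-based half-open (BED convention), one row per site,
#' stated in the file header.
#'
#' @param per_site Named list of per-site depth vectors (names
#'   `species:locus`).
#' @param path Output path.
#' @param header_note Optional provenance comment.
#' @export
write_depth_bed <- function(per_site, path, header_note = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates are 0-based half-open (BED convention)", con)
  if (!is.null(header_note)) writeLines(paste0("# ", header_note), con)
  writeLines("locus\tstart\tend\tdepth", con)
  for (nm in names(per_site)) {
    d <- per_site[[nm]]
    writeLines(sprintf("%s\t%d\t%d\t%d", nm, seq_along(d) - 1L,
                       seq_along(d), d), con)
  }
  invisible(path)
}

pipeline_defaults <- function() {
  list(
    seed = NULL, outdir = NULL,
    stages = c("simulate", "call", "classify", "tree", "events"),
    # simulator
    birth_rate = 0.01, disruption_rate = 0.02, loss_rate = 0.01,
    conversion_rate = 0.1, root_repertoire_size = 32,
    subst_rate = 0.002, gene_rate_multiplier = 0.4, het_rate = 0.004,
    disruption_mix = 0.5, seg_pseudo_prob = 0.3, unphased_prob = 0.1,
    depth_mean = 1000, depth_dispersion = 10, sigma_locus = 0.1,
    read_len = 150, sex = "male", n_nr_a = 83, n_nr_x = 3,
    # caller thresholds (strict comparisons throughout)
    absent_depth = 10, lower_whisker_factor = 0.5,
    upper_whisker_factor = 1.5, min_gene_length = 750,
    min_nr_length = 1000, shared_threshold = 0.10,
    # classifier
    min_orf = 750, tm_required = 7,
    # trees
    bootstrap_replicates = 1000,
    tree = NULL)
}

#' Run the simulate -> call -> classify -> tree -> events pipeline
#'
#' Executes the requested stages in order on a single configuration list,
#' writes every intermediate to `outdir`, and returns a run report whose
#' per-stage counts reconcile (records in = retained + excluded). With a
#' fixed `seed` the outputs are identical across runs.
#'
#' @param config Named list; unknown keys are rejected before any stage
#'   runs. Mandatory: `seed`, `outdir`. See `bitterfam:::pipeline_defaults()`
#'   for the full key set and defaults; thresholds default to the
#'   screening constants (absence depth 10, half lower whisker, 1.5 upper
#'   whisker, 750 bp gene length, 1000 bp reference length, 0.10 shared
#'   fraction, 7 TM, 1000 bootstrap replicates).
#' @return A list of class `run_report`.
#' @export
run_pipeline <- function(config) {
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$seed)) stop("config must set 'seed'")
  if (is.null(cfg$outdir)) stop("config must set 'outdir'")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  note <- paste0("seed=", cfg$seed)

  tree <- if (is.null(cfg$tree)) {
    phy <- ape::read.tree(text =
      "(((A:2,B:2):2,(C:2,D:2):2):2,(E:3,F:3):3):1;")
    species_tree(phy)
  } else cfg$tree

  report <- list(seed = cfg$seed, stages = list())
  sim <- emission <- calls <- statuses <- NULL

  if ("simulate" %in% cfg$stages) {
    scfg <- simulation_config(
      birth_rate = cfg$birth_rate, disruption_rate = cfg$disruption_rate,
      loss_rate = cfg$loss_rate, conversion_rate = cfg$conversion_rate,
      root_repertoire_size = cfg$root_repertoire_size,
      subst_rate = cfg$subst_rate,
      gene_rate_multiplier = cfg$gene_rate_multiplier,
      het_rate = cfg$het_rate, disruption_mix = cfg$disruption_mix,
      seg_pseudo_prob = cfg$seg_pseudo_prob,
      unphased_prob = cfg$unphased_prob, depth_mean = cfg$depth_mean,
      depth_dispersion = cfg$depth_dispersion,
      sigma_locus = cfg$sigma_locus, read_len = cfg$read_len,
      seed = cfg$seed)
    sim <- simulate_history(tree, scfg)
    emission <- emit_capture(sim, scfg, sex = cfg$sex,
                             n_nr_a = cfg$n_nr_a, n_nr_x = cfg$n_nr_x)
    jsonlite::write_json(sim$history, file.path(cfg$outdir, "history.json"),
                         dataframe = "rows", pretty = TRUE)
    write_tsv(emission$records, file.path(cfg$outdir, "emission.tsv"), note)
    fa <- list()
    for (sp in names(sim$repertoires)) {
      rep_ <- sim$repertoires[[sp]]
      for (g in rep_$genes$gene_id) {
        st <- rep_$genes$state[rep_$genes$gene_id == g]
        fa[[paste(sp, g, "H1", st, sep = "|")]] <- rep_$H1[[g]][rep_$H1[[g]] != "-"]
        fa[[paste(sp, g, "H2", st, sep = "|")]] <- rep_$H2[[g]][rep_$H2[[g]] != "-"]
      }
    }
    write_fasta(fa, file.path(cfg$outdir, "repertoires.fasta"), note)
    report$stages$simulate <- list(
      n_species = length(sim$repertoires),
      n_events = nrow(sim$history),
      n_records = nrow(emission$records))
  }

  if ("call" %in% cfg$stages) {
    if (is.null(emission)) stop("call stage needs a simulated emission")
    calls <- call_loci(emission, shared_threshold = cfg$shared_threshold)
    write_tsv(calls$calls, file.path(cfg$outdir, "calls.tsv"), note)
    write_tsv(calls$exclusions, file.path(cfg$outdir, "exclusions.tsv"), note)
    jsonlite::write_json(
      lapply(calls$boxplots, function(sp) lapply(sp, unclass)),
      file.path(cfg$outdir, "boxplots.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    n_gene_rec <- sum(emission$records$kind == "gene")
    report$stages$call <- list(
      records_in = n_gene_rec,
      called = sum(calls$calls$call != "absent"),
      excluded = sum(calls$calls$call == "absent"))
  }

  if ("classify" %in% cfg$stages) {
    if (is.null(calls)) stop("classify stage needs locus calls")
    statuses <- classify_genes(emission, calls, min_orf = cfg$min_orf,
                               tm_required = cfg$tm_required)
    write_tsv(statuses, file.path(cfg$outdir, "gene_status.tsv"), note)
    report$stages$classify <- list(
      n_classified = nrow(statuses),
      by_status = as.list(table(statuses$status)))
  }

  if ("tree" %in% cfg$stages) {
    if (is.null(sim)) stop("tree stage needs simulated sequences")
    aln <- list()
    for (sp in names(sim$repertoires)) {
      rep_ <- sim$repertoires[[sp]]
      for (g in rep_$genes$gene_id[!rep_$genes$born][1:min(4,
             sum(!rep_$genes$born))])
        aln[[paste(g, sp, sep = "_")]] <- rep_$H1[[g]]
    }
    bt <- bootstrap_support(aln, replicates = cfg$bootstrap_replicates,
                            seed = cfg$seed + 3L)
    write_newick(bt, file.path(cfg$outdir, "gene_tree.nwk"))
    report$stages$tree <- list(
      n_tips = length(aln),
      dropped_replicates = attr(bt, "dropped_replicates"))
  }

  if ("events" %in% cfg$stages) {
    if (is.null(sim)) stop("events stage needs a simulated history")
    matrix <- truth_status_matrix(sim)
    births <- place_births(matrix, tree, families = truth_families(sim))
    deaths <- place_deaths(matrix, tree, births)
    ledger <- rbind(births, deaths)
    counts <- count_branch_events(ledger, matrix, tree)
    totals <- ancestral_counts(cfg$root_repertoire_size, counts, tree)
    write_tsv(ledger, file.path(cfg$outdir, "ledger.tsv"), note)
    write_tsv(counts, file.path(cfg$outdir, "branch_counts.tsv"), note)
    write_tsv(totals, file.path(cfg$outdir, "node_totals.tsv"), note)
    report$stages$events <- list(
      n_events = nrow(ledger),
      by_type = as.list(table(ledger$type)))
  }

  if (!is.null(sim)) {
    report$per_species <- do.call(rbind, lapply(sim$repertoires, function(r)
      data.frame(species = r$species,
                 intact = sum(r$genes$state == "intact"),
                 segregating = sum(r$genes$state == "segregating"),
                 disrupted = sum(r$genes$state == "disrupted"),
                 lost = cfg$root_repertoire_size +
                   sum(r$genes$born) - nrow(r$genes))))
    rownames(report$per_species) <- NULL
    write_tsv(report$per_species,
              file.path(cfg$outdir, "species_summary.tsv"), note)
  }
  class(report) <- "run_report"
  report
}

# status matrix from simulator ground truth (single-locus categories)
truth_status_matrix <- function(sim) {
  rows <- list()
  for (sp in names(sim$repertoires)) {
    g <- sim$repertoires[[sp]]$genes
    if (nrow(g) == 0) next
    rows[[sp]] <- data.frame(species = sp, gene = g$gene_id,
                             status = g$state, category = NA_integer_,
                             shared_group = ifelse(g$state == "disrupted",
                                                   paste0(g$gene_id, ":", g$tag),
                                                   NA_character_))
  }
  if (length(rows) == 0)
    return(data.frame(species = character(), gene = character(),
                      status = character(), category = integer(),
                      shared_group = character()))
  do.call(rbind, rows)
}

# every gene born on the tree forms a family with its source gene
truth_families <- function(sim) {
  born <- unique(sim$history$gene_id[sim$history$event == "birth"])
  if (length(born) == 0) return(NULL)
  parents <- vapply(born, function(g) {
    sim$history$parent_gene_id[sim$history$event == "birth" &
                               sim$history$gene_id == g][1]
  }, character(1))
  fam <- rbind(
    data.frame(family = parents, gene = parents, ancestral = TRUE),
    data.frame(family = parents, gene = born, ancestral = FALSE))
  unique(fam)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed", x$seed, ")\n")
  for (st in names(x$stages)) {
    cat(" -", st, ":",
        paste(names(x$stages[[st]]),
              vapply(x$stages[[st]], function(v)
                paste(unlist(v), collapse = "/"), character(1)),
              sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$per_species)) {
    cat("Per-species repertoire summary:\n")
    print(x$per_species, row.names = FALSE)
  }
  invisible(x)
}
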