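#' Dated species tree of the ten-species cercopithecid study set
#'
#' Eight cercopithecine and two colobine species with approximate
#' divergence times (million years) and the branch-id convention used in
#' the packaged event analyses: branch 1 is the cercopithecid stem (the
#' root edge, which carries the polarity information an outgroup would
#' provide), branch 2 the cercopithecine stem, branch 3 the colobine stem;
#' branches 4-9 are the remaining internal stems (Papionini, Macaca,
#' Mmul+Mfus, Papio, Cercopithecini, Epat+Csab) and 10-19 the terminal
#' branches in the fixed species order (Mmul, Mfus, Mnig, Panu, Pham,
#' Epat, Csab, Cmit, Cpol, Sent).
#'
#' @return A [species_tree()].
#' @examples
#' tr <- cercopithecid_tree()
#' branch_of_node(tr, mrca_node(tr, c("Cpol", "Sent")))  # 3
#' @export
cercopithecid_tree <- function() {
  nwk <- paste0(
    "(((((Mmul:2,Mfus:2):3,Mnig:5):5,(Panu:4,Pham:4):6):2,",
    "((Epat:7,Csab:7):2,Cmit:9):3):6,(Cpol:11,Sent:11):7):5;")
  phy <- ape::read.tree(text = nwk)
  tr <- species_tree(phy)
  tips <- phy$tip.label
  root <- length(tips) + 1L
  clade <- function(...) ape::getMRCA(phy, match(c(...), tips))
  nodes <- c(root,
             clade("Mmul", "Cmit"),          # cercopithecine stem
             clade("Cpol", "Sent"),          # colobine stem
             clade("Mmul", "Pham"),          # Papionini
             clade("Mmul", "Mnig"),          # Macaca
             clade("Mmul", "Mfus"),
             clade("Panu", "Pham"),          # Papio
             clade("Epat", "Cmit"),          # Cercopithecini
             clade("Epat", "Csab"),
             match(tips, tips))              # terminals 10..19
  species_tree(phy, data.frame(node = nodes,
                               branch_id = seq_along(nodes)))
}

CERCO_SPECIES <- c("Mmul", "Mfus", "Mnig", "Panu", "Pham",
                   "Epat", "Csab", "Cmit", "Cpol", "Sent")
CERCOPITHECINES <- CERCO_SPECIES[1:8]
COLOBINES <- c("Cpol", "Sent")

#' Sex of each sampled individual in the study set
#'
#' @return Named character vector (`"male"`/`"female"`).
#' @export
cercopithecid_sex <- function() {
  c(Mmul = "male", Mfus = "male", Mnig = "male", Panu = "male",
    Pham = "female", Epat = "male", Csab = "male", Cmit = "female",
    Cpol = "female", Sent = "male")
}

# The 31 receptor genes intact in at least one probe-design assembly, in
# base-name form (paralog copies collapsed).
PROBED_GENES <- paste0("TAS2R", c(
  1, 2, 3, 4, 5, 7, 8, 9, 10, 13, 14, 16, 20, 38, 41, 42, 46, 50, 60,
  403, 405, 406, 407, 408, 410, 411, 412, 413, 414, 415, 419))

#' Gene status inventory of the five probe-design genome assemblies
#'
#' Per-gene intact/disrupted/absent status across the three cercopithecine
#' and two colobine whole-genome assemblies from which capture probes were
#' designed. The 31 probed genes are intact in at least one assembly
#' (a few only in a single one); TAS2R418 is disrupted in all five, which
#' is why it was not probed; three further receptor genes are absent or
#' disrupted everywhere and fall outside the ancestral set.
#'
#' @return Data frame `gene`, `database`, `status`.
#' @export
design_db_inventory <- function() {
  dbs <- c("Mmul_8.0.1", "Mfas_5.0", "Caty_1.0", "Cang.pa_1.0", "Rrox_v1")
  rows <- expand.grid(gene = PROBED_GENES, database = dbs,
                      stringsAsFactors = FALSE)
  rows$status <- "intact"
  # sparser probed genes: intact in a single assembly only
  rows$status[rows$gene == "TAS2R20" & rows$database != "Mmul_8.0.1"] <-
    "disrupted"
  rows$status[rows$gene == "TAS2R42" & rows$database != "Cang.pa_1.0"] <-
    "truncated"
  extra <- expand.grid(gene = c("TAS2R418", "TAS2R62", "TAS2R64", "TAS2R67"),
                       database = dbs, stringsAsFactors = FALSE)
  extra$status <- ifelse(extra$gene == "TAS2R418", "disrupted", "absent")
  rbind(rows, extra)
}

#' Capture-derived status matrix of the ancestral gene set
#'
#' Species-by-gene statuses encoding the species-level findings of the
#' ten-species capture study: the TAS2R405-group paralogs and the TAS2R10
#' copies as separate loci; TAS2R418 intact in anubis baboon, hamadryas
#' baboon and patas monkey only; TAS2R403 disrupted in both colobines by
#' the same mutation (annotated as shared group `"403col"`); TAS2R10-2 and
#' TAS2R413-2 missing from the colobines; capture-detected duplication
#' categories for TAS2R414/415/50/419/60/42 and the undecided high-SNP
#' loci; and a few segregating pseudogenes. Everything else is intact.
#'
#' @return Data frame `species`, `gene`, `status`, `category`,
#'   `shared_group`.
#' @export
cercopithecid_status_matrix <- function() {
  genes <- c(setdiff(PROBED_GENES, c("TAS2R10", "TAS2R413")),
             "TAS2R10-1", "TAS2R10-2", "TAS2R413-1", "TAS2R413-2",
             "TAS2R418")
  m <- expand.grid(species = CERCO_SPECIES, gene = genes,
                   stringsAsFactors = FALSE)
  m$status <- "intact"
  m$category <- NA_integer_
  m$shared_group <- NA_character_
  set_ <- function(m, gene, species, status = NULL, category = NULL,
                   group = NULL) {
    i <- m$gene == gene & m$species %in% species
    if (!is.null(status)) m$status[i] <- status
    if (!is.null(category)) m$category[i] <- category
    if (!is.null(group)) m$shared_group[i] <- group
    m
  }
  # colobine-stem losses and the shared colobine disruption
  m <- set_(m, "TAS2R10-2", COLOBINES, status = "absent")
  m <- set_(m, "TAS2R413-2", COLOBINES, status = "absent")
  m <- set_(m, "TAS2R418", COLOBINES, status = "absent")
  m <- set_(m, "TAS2R403", COLOBINES, status = "disrupted", group = "403col")
  # TAS2R418 was retrieved intact only in the two baboons and the patas
  m <- set_(m, "TAS2R418", c("Mmul", "Mfus", "Mnig", "Csab", "Cmit"),
            status = "absent")
  # capture-detected duplications (categories 1-3) and undecided loci
  m <- set_(m, "TAS2R414", c("Mmul", "Mfus"), category = 1L)
  m <- set_(m, "TAS2R414", "Mnig", category = 3L)
  m <- set_(m, "TAS2R414", "Panu", category = 2L)
  m <- set_(m, "TAS2R414", "Csab", category = 1L)
  m <- set_(m, "TAS2R415", c("Mmul", "Mfus", "Panu"), category = 2L)
  m <- set_(m, "TAS2R415", c("Mnig", "Cmit"), category = 3L)
  m <- set_(m, "TAS2R415", c("Epat", "Csab"), category = 1L)
  m <- set_(m, "TAS2R50", "Panu", category = 2L)
  m <- set_(m, "TAS2R419", "Pham", category = 2L)
  m <- set_(m, "TAS2R419", "Epat", category = 4L)
  m <- set_(m, "TAS2R60", "Sent", category = 2L)
  m <- set_(m, "TAS2R14", "Sent", category = 4L)
  m <- set_(m, "TAS2R42", "Cpol", status = "intact_and_disrupted",
            category = 3L)
  m <- set_(m, "TAS2R412", "Cpol", status = "intact_and_disrupted",
            category = 4L)
  m <- set_(m, "TAS2R20", "Mfus", category = 4L)
  # segregating pseudogenes reported in single species
  m <- set_(m, "TAS2R5", "Mmul", status = "segregating")
  m <- set_(m, "TAS2R413-1", "Mmul", status = "segregating")
  m <- set_(m, "TAS2R60", "Csab", status = "segregating")
  m <- set_(m, "TAS2R419", "Sent", status = "segregating")
  m
}

#' Ancient paralog families of the ancestral gene set
#'
#' The nine-member TAS2R405 group (TAS2R410, 411, 412, 413-1, 413-2, 414,
#' 415, 418, 419) descends from a single pre-cercopithecid ancestor; under
#' the gene-conversion parsimony this costs eight births, with TAS2R418
#' carrying the unduplicated ancestral lineage. The TAS2R10 pair costs one
#' birth (TAS2R10-2).
#'
#' @return Data frame `family`, `gene`, `ancestral`.
#' @export
tas2r_families <- function() {
  g405 <- c("TAS2R418", "TAS2R410", "TAS2R411", "TAS2R412", "TAS2R413-1",
            "TAS2R413-2", "TAS2R414", "TAS2R415", "TAS2R419")
  rbind(
    data.frame(family = "TAS2R405group", gene = g405,
               ancestral = g405 == "TAS2R418"),
    data.frame(family = "TAS2R10", gene = c("TAS2R10-1", "TAS2R10-2"),
               ancestral = c(TRUE, FALSE)))
}

#' Prior-knowledge events for the cercopithecid ledger
#'
#' Placements asserted from earlier literature and from gene trees that
#' include database genomes, which the captured-species status matrix
#' alone cannot polarize: the cercopithecid-stem (branch 1) births of
#' TAS2R413-2 and TAS2R10-2 (both copies were subsequently lost in the
#' colobines, so their capture pattern underdetermines the placement), the
#' TAS2R409-derived duplication giving TAS2R404 with its loss on the same
#' branch, the TAS2R15 disruption on branch 1, and the cercopithecine-stem
#' (branch 2) placement of the TAS2R50 duplication.
#'
#' @return Data frame `branch_id`, `type`, `gene`, `note`.
#' @export
cercopithecid_prior_events <- function() {
  data.frame(
    branch_id = c(1L, 1L, 1L, 1L, 1L, 2L),
    type = c("birth", "birth", "birth", "loss", "disruption", "birth"),
    gene = c("TAS2R413-2", "TAS2R10-2", "TAS2R404", "TAS2R404",
             "TAS2R15", "TAS2R50-dup"),
    note = c("gene-tree placement incl. database genomes",
             "gene-tree placement incl. database genomes",
             "duplication of TAS2R409; earlier literature",
             "lost on the same branch; earlier literature",
             "earlier literature",
             "gene-tree placement incl. database genomes"))
}

#' Reconstruct the cercopithecid birth-death ledger from the fixture
#'
#' Convenience wrapper running [place_births()] on the packaged status
#' matrix and families, merging [cercopithecid_prior_events()] (prior
#' placements win where the capture pattern underdetermines them), and
#' running [place_deaths()] on the merged ledger.
#'
#' @return A list: `ledger` (all events), `counts`
#'   ([count_branch_events()] result), `tree`, `matrix`.
#' @examples
#' led <- cercopithecid_ledger()
#' subset(led$counts, branch_id %in% 1:3)
#' @export
cercopithecid_ledger <- function() {
  tree <- cercopithecid_tree()
  matrix <- cercopithecid_status_matrix()
  births <- place_births(matrix, tree, tas2r_families())
  merged <- merge_prior(births, cercopithecid_prior_events(),
                        override = TRUE)
  deaths <- place_deaths(matrix, tree, merged)
  ledger <- rbind(merged, deaths)
  counts <- count_branch_events(ledger, matrix, tree)
  list(ledger = ledger, counts = counts, tree = tree, matrix = matrix)
}

#' Per-species capture vs database sequencing depth summary
#'
#' Reads the packaged table of average per-site sequencing depths of
#' single-locus ancestral genes per species, as achieved by the targeted
#' capture (TC) and as available in each species' public whole-genome
#' assembly (WGA; not available for the king colobus).
#'
#' @return Data frame `species`, `common_name`, `tc_depth`, `wga_depth`.
#' @export
capture_depth_table <- function() {
  path <- system.file("extdata", "capture_depth_summary.tsv",
                      package = "bitterfam", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
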