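# Synthetic bridged disease-gene-drug benchmarks with planted father-son
# drug sharing. The generator plants exactly the mechanism the biased walk
# is meant to exploit: a son disease shares a subset of its father's genes
# and, with probability p_share, the father's therapeutic drugs; a fraction
# of those shared son-drug links is withheld as test queries whose answer is
# reachable through the bridge in training.

#' Benchmark generator configuration
#'
#' @param n_fathers number of father diseases (network 1).
#' @param sons_per_father son diseases per father (network 2).
#' @param n_genes,n_drugs pool sizes.
#' @param genes_per_disease pathogenic gene links per disease.
#' @param drugs_per_father therapeutic drug links per father.
#' @param p_share probability that a father's drug also treats the son.
#' @param p_noise probability of a spurious disease-drug edge.
#' @param holdout_fraction fraction of shared son-drug links withheld as test
#'   queries, in (0, 1).
#' @param gene_inherit fraction of the father's genes a son inherits.
#' @param seed integer seed; the benchmark is fully reproducible from it.
#' @return object of class `benchmark_config`.
#' @export
benchmark_config <- function(n_fathers = 20L, sons_per_father = 1L,
                             n_genes = 40L, n_drugs = 30L,
                             genes_per_disease = 3L, drugs_per_father = 2L,
                             p_share = 0.8, p_noise = 0.05,
                             holdout_fraction = 0.5, gene_inherit = 0.5,
                             seed = 1L) {
  counts <- c(n_fathers = n_fathers, sons_per_father = sons_per_father,
              n_genes = n_genes, n_drugs = n_drugs,
              genes_per_disease = genes_per_disease,
              drugs_per_father = drugs_per_father)
  if (any(counts < 1)) {
    stopf("counts must be positive; offending: %s",
          paste(names(counts)[counts < 1], collapse = ", "))
  }
  probs <- c(p_share = p_share, p_noise = p_noise, gene_inherit = gene_inherit)
  if (any(probs < 0 | probs > 1)) {
    stopf("probabilities must lie in [0, 1]; offending: %s",
          paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  }
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    stopf("holdout_fraction must lie in (0, 1)")
  }
  if (genes_per_disease > n_genes) {
    stopf("genes_per_disease (%d) exceeds n_genes (%d)", genes_per_disease, n_genes)
  }
  if (drugs_per_father > n_drugs) {
    stopf("drugs_per_father (%d) exceeds n_drugs (%d)", drugs_per_father, n_drugs)
  }
  structure(list(n_fathers = as.integer(n_fathers),
                 sons_per_father = as.integer(sons_per_father),
                 n_genes = as.integer(n_genes), n_drugs = as.integer(n_drugs),
                 genes_per_disease = as.integer(genes_per_disease),
                 drugs_per_father = as.integer(drugs_per_father),
                 p_share = p_share, p_noise = p_noise,
                 holdout_fraction = holdout_fraction,
                 gene_inherit = gene_inherit, seed = as.integer(seed)),
            class = "benchmark_config")
}

#' Generate a planted-signal benchmark
#'
#' Construction: each father gets `genes_per_disease` pathogenic gene links
#' and `drugs_per_father` therapeutic drug links in network 1. Each son
#' inherits `gene_inherit` of the father's genes (topped up with fresh genes
#' to the same count) in network 2 and, with probability `p_share`, each of
#' the father's drugs. Spurious disease-drug edges are added with probability
#' `p_noise` per (disease, drug) pair. A `holdout_fraction` of the shared
#' son-drug links is withheld as test triples; their father-side counterparts
#' always remain in training, so the signal is recoverable through the
#' bridge.
#'
#' @param config a `benchmark_config`.
#' @return object of class `gcan_benchmark`: `triples1`, `triples2` (training
#'   graphs), `bridge` (`gcan_bridge`), `types`, `train` (union of the two
#'   triple sets), `test` (withheld therapeutic triples, network 2), `shared`
#'   (ground-truth share list with a `withheld` flag), `config`.
#' @export
generate_benchmark <- function(config) {
  cf <- config
  fathers <- sprintf("father_%03d", seq_len(cf$n_fathers))
  sons <- as.vector(vapply(seq_len(cf$n_fathers), function(i) {
    sprintf("son_%03d_%d", i, seq_len(cf$sons_per_father))
  }, character(cf$sons_per_father)))
  son_father <- rep(fathers, each = cf$sons_per_father)
  genes <- sprintf("gene_%03d", seq_len(cf$n_genes))
  drugs <- sprintf("drug_%03d", seq_len(cf$n_drugs))

  with_seed(derive_seed(cf$seed, "benchmark"), {
    t1_head <- character(); t1_rel <- character(); t1_tail <- character()
    father_genes <- list(); father_drugs <- list()
    for (f in fathers) {
      fg <- sample(genes, cf$genes_per_disease)
      fd <- sample(drugs, cf$drugs_per_father)
      father_genes[[f]] <- fg
      father_drugs[[f]] <- fd
      t1_head <- c(t1_head, rep(f, length(fg) + length(fd)))
      t1_rel <- c(t1_rel, rep("pathogenic", length(fg)),
                  rep("therapeutic", length(fd)))
      t1_tail <- c(t1_tail, fg, fd)
    }
    t2_head <- character(); t2_rel <- character(); t2_tail <- character()
    sh_son <- character(); sh_drug <- character()
    n_inherit <- round(cf$gene_inherit * cf$genes_per_disease)
    for (i in seq_along(sons)) {
      s <- sons[i]; f <- son_father[i]
      inh <- if (n_inherit > 0) sample(father_genes[[f]], n_inherit) else character()
      fresh_pool <- setdiff(genes, inh)
      fresh <- sample(fresh_pool, cf$genes_per_disease - length(inh))
      sg <- c(inh, fresh)
      t2_head <- c(t2_head, rep(s, length(sg)))
      t2_rel <- c(t2_rel, rep("pathogenic", length(sg)))
      t2_tail <- c(t2_tail, sg)
      shared <- father_drugs[[f]][stats::runif(cf$drugs_per_father) < cf$p_share]
      sh_son <- c(sh_son, rep(s, length(shared)))
      sh_drug <- c(sh_drug, shared)
    }
    if (length(sh_son) == 0) {
      stopf("no shared son-drug links were generated (p_share = %.3f): the benchmark carries no signal",
            cf$p_share)
    }
    shared_df <- data.frame(son = sh_son, drug = sh_drug,
                            stringsAsFactors = FALSE)
    n_test <- floor(cf$holdout_fraction * nrow(shared_df))
    withheld <- rep(FALSE, nrow(shared_df))
    if (n_test > 0) withheld[sample.int(nrow(shared_df), n_test)] <- TRUE
    shared_df$withheld <- withheld

    # spurious disease-drug edges; never duplicate a withheld test pair
    noise1 <- which(matrix(stats::runif(length(fathers) * length(drugs)),
                           length(fathers)) < cf$p_noise, arr.ind = TRUE)
    noise2 <- which(matrix(stats::runif(length(sons) * length(drugs)),
                           length(sons)) < cf$p_noise, arr.ind = TRUE)
    if (nrow(noise1) > 0) {
      t1_head <- c(t1_head, fathers[noise1[, 1]])
      t1_rel <- c(t1_rel, rep("therapeutic", nrow(noise1)))
      t1_tail <- c(t1_tail, drugs[noise1[, 2]])
    }
    kept <- shared_df[!shared_df$withheld, , drop = FALSE]
    t2_head <- c(t2_head, kept$son)
    t2_rel <- c(t2_rel, rep("therapeutic", nrow(kept)))
    t2_tail <- c(t2_tail, kept$drug)
    if (nrow(noise2) > 0) {
      n2 <- data.frame(son = sons[noise2[, 1]], drug = drugs[noise2[, 2]],
                       stringsAsFactors = FALSE)
      test_key <- paste(shared_df$son[shared_df$withheld],
                        shared_df$drug[shared_df$withheld])
      n2 <- n2[!paste(n2$son, n2$drug) %in% test_key, , drop = FALSE]
      t2_head <- c(t2_head, n2$son)
      t2_rel <- c(t2_rel, rep("therapeutic", nrow(n2)))
      t2_tail <- c(t2_tail, n2$drug)
    }
    triples1 <- triples(t1_head, t1_rel, t1_tail, 1L)
    triples2 <- triples(t2_head, t2_rel, t2_tail, 2L)
    test <- triples(shared_df$son[shared_df$withheld], "therapeutic",
                    shared_df$drug[shared_df$withheld], 2L)
    types <- entity_types(c(
      stats::setNames(rep("disease", length(fathers) + length(sons)),
                      c(fathers, sons)),
      stats::setNames(rep("gene", length(genes)), genes),
      stats::setNames(rep("drug", length(drugs)), drugs)))
    bridge <- bridge_map(son_father, sons, triples1, triples2)
    structure(list(triples1 = triples1, triples2 = triples2, bridge = bridge,
                   types = types, train = rbind(triples1, triples2),
                   test = test, shared = shared_df, config = cf),
              class = "gcan_benchmark")
  })
}

#' @export
print.gcan_benchmark <- function(x, ...) {
  cat(sprintf("<gcan_benchmark> %d + %d training triples, %d bridge pairs, %d test queries\n",
              nrow(x$triples1), nrow(x$triples2), nrow(x$bridge$pairs),
              nrow(x$test)))
  invisible(x)
}

#' Build the bridged network of a benchmark's training graphs
#' @param benchmark a `gcan_benchmark`.
#' @return a `bridged_network`.
#' @export
benchmark_network <- function(benchmark) {
  build_bridged_network(benchmark$triples1, benchmark$triples2,
                        benchmark$types, benchmark$bridge)
}

#' Hand-written Gaucher-style worked fixture
#'
#' A miniature of the motivating case: father disease `gaucher_type_I`
#' (network 1) and son `gaucher_type_III` (network 2) are bridged and share
#' the gene `GBA`; the drugs `imiglucerase` and `taliglucerase_alfa` treat
#' type I in training, and the two corresponding type-III therapeutic links
#' are the test queries. Deterministic distractor father-son disease pairs
#' with their own genes and drugs (sons inheriting one paternal drug in
#' training, so the sharing pattern is learnable) pad the candidate set to
#' 20 drugs.
#'
#' @param n_distractors number of distractor father-son pairs (each
#'   contributes 2 drugs).
#' @return a `gcan_benchmark` with 2 test queries.
#' @export
gaucher_fixture <- function(n_distractors = 9L) {
  n_distractors <- as.integer(n_distractors)
  if (n_distractors < 0L) stopf("n_distractors must be >= 0")
  t1 <- list(head = c("gaucher_type_I", "gaucher_type_I", "gaucher_type_I"),
             rel = c("pathogenic", "therapeutic", "therapeutic"),
             tail = c("GBA", "imiglucerase", "taliglucerase_alfa"))
  t2 <- list(head = "gaucher_type_III", rel = "pathogenic", tail = "GBA")
  fathers <- "gaucher_type_I"; sons <- "gaucher_type_III"
  diseases <- c("gaucher_type_I", "gaucher_type_III")
  genes <- "GBA"
  drugs <- c("imiglucerase", "taliglucerase_alfa")
  for (i in seq_len(n_distractors)) {
    f <- sprintf("dis_father_%02d", i); s <- sprintf("dis_son_%02d", i)
    g <- sprintf("dis_gene_%02d", i)
    d1 <- sprintf("dis_drug_%02d_a", i); d2 <- sprintf("dis_drug_%02d_b", i)
    t1$head <- c(t1$head, f, f, f)
    t1$rel <- c(t1$rel, "pathogenic", "therapeutic", "therapeutic")
    t1$tail <- c(t1$tail, g, d1, d2)
    # distractor sons exhibit the father-drug-sharing pattern in training:
    # both paternal drugs treat the son, as in the motivating case
    t2$head <- c(t2$head, s, s, s)
    t2$rel <- c(t2$rel, "pathogenic", "therapeutic", "therapeutic")
    t2$tail <- c(t2$tail, g, d1, d2)
    fathers <- c(fathers, f); sons <- c(sons, s)
    diseases <- c(diseases, f, s); genes <- c(genes, g)
    drugs <- c(drugs, d1, d2)
  }
  triples1 <- triples(t1$head, t1$rel, t1$tail, 1L)
  triples2 <- triples(t2$head, t2$rel, t2$tail, 2L)
  test <- triples(c("gaucher_type_III", "gaucher_type_III"), "therapeutic",
                  c("imiglucerase", "taliglucerase_alfa"), 2L)
  types <- entity_types(c(
    stats::setNames(rep("disease", length(diseases)), diseases),
    stats::setNames(rep("gene", length(genes)), genes),
    stats::setNames(rep("drug", length(drugs)), drugs)))
  bridge <- bridge_map(fathers, sons, triples1, triples2)
  shared <- data.frame(son = c("gaucher_type_III", "gaucher_type_III"),
                       drug = c("imiglucerase", "taliglucerase_alfa"),
                       withheld = TRUE, stringsAsFactors = FALSE)
  structure(list(triples1 = triples1, triples2 = triples2, bridge = bridge,
                 types = types, train = rbind(triples1, triples2),
                 test = test, shared = shared, config = NULL),
            class = "gcan_benchmark")
}

#' Write a benchmark to a directory
#'
#' Emits `hn1.tsv`, `hn2.tsv`, `bridge.tsv`, `types.tsv`, `train.tsv`,
#' `test.tsv` in the standard TSV formats plus `manifest.json` recording the
#' generating configuration. Output is sorted, so identical benchmarks write
#' byte-identical files.
#'
#' @param benchmark a `gcan_benchmark`.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(benchmark, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("cannot create directory: %s", dir)
  }
  write_triples(benchmark$triples1, file.path(dir, "hn1.tsv"))
  write_triples(benchmark$triples2, file.path(dir, "hn2.tsv"))
  write_triples(benchmark$train, file.path(dir, "train.tsv"))
  write_triples(benchmark$test, file.path(dir, "test.tsv"))
  pr <- benchmark$bridge$pairs
  pr <- pr[order(pr$father, pr$son, method = "radix"), , drop = FALSE]
  atomic_write(function(p) {
    writeLines(paste(pr$father, pr$son, sep = "\t"), p, useBytes = TRUE)
  }, file.path(dir, "bridge.tsv"))
  ty <- benchmark$types[order(names(benchmark$types), method = "radix")]
  atomic_write(function(p) {
    writeLines(paste(names(ty), ty, sep = "\t"), p, useBytes = TRUE)
  }, file.path(dir, "types.tsv"))
  atomic_write(function(p) {
    jsonlite::write_json(list(format = "gcan-benchmark", version = 1L,
                              config = if (!is.null(benchmark$config))
                                unclass(benchmark$config)),
                         p, auto_unbox = TRUE, digits = NA, null = "null")
  }, file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Read a benchmark directory written by [write_benchmark()]
#' @param dir benchmark directory.
#' @return a `gcan_benchmark` (without the ground-truth share list).
#' @export
read_benchmark <- function(dir) {
  triples1 <- read_triples(file.path(dir, "hn1.tsv"), 1L)
  triples2 <- read_triples(file.path(dir, "hn2.tsv"), 2L)
  types <- read_entity_types(file.path(dir, "types.tsv"))
  bridge <- read_bridge(file.path(dir, "bridge.tsv"), triples1, triples2)
  test <- read_triples(file.path(dir, "test.tsv"), 2L)
  manifest_path <- file.path(dir, "manifest.json")
  cf <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)$config
  }
  structure(list(triples1 = triples1, triples2 = triples2, bridge = bridge,
                 types = types, train = rbind(triples1, triples2),
                 test = test, shared = NULL, config = cf),
            class = "gcan_benchmark")
}
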