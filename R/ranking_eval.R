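# Drug-ranking evaluation: build queries from held-out therapeutic triples,
# score all drug entities for each disease query, and report Hits@k / MRR.

#' Build ranking queries from held-out triples
#'
#' One query per therapeutic test triple (disease head, drug tail).
#' Non-therapeutic triples are skipped with a logged count. Duplicate test
#' triples yield duplicate queries, which the metrics then weight twice. The
#' candidate set is all drug-typed entities of both networks.
#'
#' @param test_triples a `gcan_triples` data frame of held-out facts.
#' @param network the `bridged_network` (supplies entity types).
#' @return object of class `gcan_queries`: data frame `queries` (columns
#'   `disease`, `relation`, `true_drug`) plus `candidates` (character vector
#'   of all drug entities).
#' @export
make_queries <- function(test_triples, network) {
  candidates <- entities_of_type(network, "drug")
  if (length(candidates) == 0) stopf("network contains no drug entities")
  ty <- network$types
  is_ther <- !is.na(ty[test_triples$head]) & ty[test_triples$head] == "disease" &
    !is.na(ty[test_triples$tail]) & ty[test_triples$tail] == "drug"
  n_skip <- sum(!is_ther)
  if (n_skip > 0) {
    gcan_log("info", "skipped %d non-therapeutic test triple(s)", n_skip)
  }
  q <- test_triples[is_ther, , drop = FALSE]
  queries <- data.frame(disease = q$head, relation = q$relation,
                        true_drug = q$tail, stringsAsFactors = FALSE)
  rownames(queries) <- NULL
  structure(list(queries = queries, candidates = candidates),
            class = "gcan_queries")
}

#' Score all candidate drugs for one query
#'
#' Embeds the disease token, steps the model through the relation token, and
#' scores each candidate drug by the dot product of the resulting prediction
#' vector with the candidate's embedding.
#'
#' @param model a `gcan_model`.
#' @param disease,relation the query prefix tokens.
#' @param candidates character vector of candidate drug entities.
#' @return named numeric vector of scores, or `NULL` (logged) when the
#'   disease or relation is not in the model vocabulary — the query is
#'   unanswerable and receives the worst rank.
#' @export
score_query <- function(model, disease, relation, candidates) {
  lk <- model$vocab$lookup
  if (is.na(lk[disease]) || is.na(lk[relation])) {
    gcan_log("warn", "unanswerable query (unseen token): %s / %s",
             disease, relation)
    return(NULL)
  }
  cand_idx <- lk[candidates]
  if (anyNA(cand_idx)) {
    stopf("candidate drug not in vocabulary: %s", candidates[is.na(cand_idx)][1])
  }
  inputs <- matrix(c(lk[[disease]], lk[[relation]]) + 1L, 1L, 2L)
  fw <- .forward_batch(inputs, model$params,
                       cooperation = model$config$cooperation,
                       attention = model$config$attention)
  z <- fw$Z[[2L]][1L, ]
  stats::setNames(as.numeric(model$params$E[cand_idx + 1L, , drop = FALSE] %*% z),
                  candidates)
}

#' Rank of the true drug among scored candidates
#'
#' Pessimistic tie handling: the true item is ranked after every other
#' candidate with an equal score, so tied scores never inflate the metrics.
#' In filtered mode, other drugs already known (from training) to treat the
#' same disease are removed from the candidate list first.
#'
#' @param scores named numeric vector over candidates.
#' @param true_drug name of the true drug (must be among the candidates).
#' @param mode `"raw"` or `"filtered"`.
#' @param train_positives drugs known from training to treat this disease
#'   (used only in filtered mode; the true drug itself is never removed).
#' @return integer rank, 1-based.
#' @export
rank_of_true <- function(scores, true_drug, mode = c("raw", "filtered"),
                         train_positives = character()) {
  mode <- match.arg(mode)
  if (!true_drug %in% names(scores)) stopf("true drug '%s' not scored", true_drug)
  if (any(!is.finite(scores))) stopf("non-finite candidate scores")
  if (mode == "filtered") {
    drop <- setdiff(intersect(names(scores), train_positives), true_drug)
    scores <- scores[setdiff(names(scores), drop)]
  }
  s_true <- scores[[true_drug]]
  as.integer(sum(scores >= s_true))
}

#' Fraction of queries whose true drug ranks within the top k
#' @param ranks integer vector of 1-based ranks.
#' @param k cutoff.
#' @return fraction in `[0, 1]`.
#' @export
hits_at_k <- function(ranks, k) {
  if (length(ranks) == 0) stopf("no ranks supplied")
  mean(ranks <= k)
}

#' Mean reciprocal rank
#' @param ranks integer vector of 1-based ranks.
#' @return MRR in `(0, 1]`.
#' @export
mrr <- function(ranks) {
  if (length(ranks) == 0) stopf("no ranks supplied")
  mean(1 / ranks)
}

# training positives per disease: drugs linked to the disease by any triple
# of the training graph, in either direction
.train_positive_map <- function(network) {
  tr <- rbind(network$triples1, network$triples2)
  ty <- network$types
  a <- tr[ty[tr$head] == "disease" & ty[tr$tail] == "drug",
          c("head", "tail"), drop = FALSE]
  b <- tr[ty[tr$tail] == "disease" & ty[tr$head] == "drug",
          c("tail", "head"), drop = FALSE]
  names(b) <- c("head", "tail")
  dd <- rbind(a, b)
  if (nrow(dd) == 0) return(list())
  split(dd$tail, dd$head)
}

#' Evaluate drug-ranking performance on held-out triples
#'
#' @param model a `gcan_model`.
#' @param test_triples held-out `gcan_triples`.
#' @param network the `bridged_network` used for training.
#' @param mode `"raw"` (default; no candidates removed) or `"filtered"`
#'   (training positives of the same disease removed before ranking).
#' @return object of class `ranking_report`: `per_query` data frame
#'   (`disease`, `relation`, `true_drug`, `rank`), `n_queries`, `mode`,
#'   `n_candidates`, `hits` (named vector for k = 1, 3, 10), `mrr`.
#' @export
evaluate_ranking <- function(model, test_triples, network,
                             mode = c("raw", "filtered")) {
  mode <- match.arg(mode)
  qs <- make_queries(test_triples, network)
  if (nrow(qs$queries) == 0) {
    stopf("no therapeutic test triples to evaluate")
  }
  pos_map <- if (mode == "filtered") .train_positive_map(network) else list()
  ranks <- integer(nrow(qs$queries))
  for (i in seq_len(nrow(qs$queries))) {
    q <- qs$queries[i, ]
    sc <- score_query(model, q$disease, q$relation, qs$candidates)
    if (is.null(sc)) {
      n_c <- length(qs$candidates)
      if (mode == "filtered") {
        n_c <- n_c - length(setdiff(intersect(qs$candidates,
                                              pos_map[[q$disease]] %||% character()),
                                    q$true_drug))
      }
      ranks[i] <- n_c
    } else {
      ranks[i] <- rank_of_true(sc, q$true_drug, mode,
                               pos_map[[q$disease]] %||% character())
    }
  }
  per_query <- cbind(qs$queries, rank = ranks)
  structure(list(per_query = per_query, n_queries = nrow(per_query),
                 n_candidates = length(qs$candidates), mode = mode,
                 hits = c(`1` = hits_at_k(ranks, 1),
                          `3` = hits_at_k(ranks, 3),
                          `10` = hits_at_k(ranks, 10)),
                 mrr = mrr(ranks)),
            class = "ranking_report")
}

#' @export
print.ranking_report <- function(x, ...) {
  cat(sprintf(paste0("<ranking_report> %d queries over %d candidates (%s)\n",
                     "  Hits@1 %.3f  Hits@3 %.3f  Hits@10 %.3f  MRR %.3f\n"),
              x$n_queries, x$n_candidates, x$mode,
              x$hits[["1"]], x$hits[["3"]], x$hits[["10"]], x$mrr))
  invisible(x)
}

#' Write a ranking report to JSON plus a per-query TSV
#'
#' @param report a `ranking_report`.
#' @param json_path,tsv_path destinations (written atomically).
#' @export
write_report <- function(report, json_path, tsv_path) {
  obj <- list(n_queries = report$n_queries, mode = report$mode,
              n_candidates = report$n_candidates,
              `hits@1` = report$hits[["1"]], `hits@3` = report$hits[["3"]],
              `hits@10` = report$hits[["10"]], mrr = report$mrr)
  atomic_write(function(p) {
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA)
  }, json_path)
  atomic_write(function(p) {
    utils::write.table(report$per_query, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }, tsv_path)
  invisible(c(json_path, tsv_path))
}
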