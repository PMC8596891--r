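# Data model and I/O for the two heterogeneous disease-gene-drug networks,
# the father-son bridge between them, entity typing, and the token
# vocabulary shared by the walk sampler and the sequence model.

#' Default relation token emitted for cross-network (father-son) steps
#' @export
GCAN_BRIDGE_TOKEN <- "__FATHER_SON__"

.read_tsv_lines <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Read network triples from a TSV file
#'
#' Each non-comment line holds one `(head, relation, tail)` fact, tab
#' separated. Lines starting with `#` are ignored. Duplicate lines are
#' collapsed to a single triple (the walk kernel assigns one probability per
#' neighbor, so multiplicity must not bias it); the number dropped is logged.
#'
#' @param path path to a 3-column TSV file (head, relation, tail; no header).
#' @param network_id which of the two heterogeneous networks the file
#'   describes: `1` (father-node network) or `2` (son-node network).
#' @return a `data.frame` of class `gcan_triples` with columns `head`,
#'   `relation`, `tail`, `network_id`.
#' @export
read_triples <- function(path, network_id) {
  network_id <- as.integer(network_id)
  if (!network_id %in% c(1L, 2L)) stopf("network_id must be 1 or 2")
  tsv <- .read_tsv_lines(path)
  parts <- strsplit(tsv$lines, "\t", fixed = TRUE)
  ncol_each <- lengths(parts)
  bad <- which(ncol_each != 3L)
  if (length(bad) > 0) {
    stopf("malformed triple (expected 3 tab-separated columns, got %d) at line %d of %s",
          ncol_each[bad[1]], tsv$lineno[bad[1]], path)
  }
  m <- do.call(rbind, parts)
  loops <- which(m[, 1] == m[, 3])
  if (length(loops) > 0) {
    stopf("self-loop triple (head == tail, '%s') at line %d of %s",
          m[loops[1], 1], tsv$lineno[loops[1]], path)
  }
  df <- data.frame(head = m[, 1], relation = m[, 2], tail = m[, 3],
                   network_id = network_id, stringsAsFactors = FALSE)
  dup <- duplicated(df)
  if (any(dup)) {
    gcan_log("info", "dropped %d duplicate triple line(s) from %s", sum(dup), path)
    df <- df[!dup, , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("gcan_triples", "data.frame")
  df
}

#' Construct triples in code
#'
#' @param head,relation,tail character vectors of equal length.
#' @param network_id `1` or `2`, recycled.
#' @return a `gcan_triples` data frame (deduplicated, self-loops rejected).
#' @export
triples <- function(head, relation, tail, network_id) {
  n <- length(head)
  df <- data.frame(head = as.character(head),
                   relation = rep_len(as.character(relation), n),
                   tail = as.character(tail),
                   network_id = rep_len(as.integer(network_id), n),
                   stringsAsFactors = FALSE)
  if (any(df$head == df$tail)) stopf("self-loop triple: %s", df$head[df$head == df$tail][1])
  df <- unique(df)
  rownames(df) <- NULL
  class(df) <- c("gcan_triples", "data.frame")
  df
}

#' Write triples to TSV (sorted, deduplicated)
#'
#' Output is sorted so that `write_triples(read_triples(f))` reproduces the
#' deduplicated file modulo line order.
#'
#' @param x a `gcan_triples` data frame.
#' @param path destination path (written atomically).
#' @export
write_triples <- function(x, path) {
  ord <- order(x$head, x$relation, x$tail, method = "radix")
  x <- x[ord, , drop = FALSE]
  atomic_write(function(p) {
    writeLines(paste(x$head, x$relation, x$tail, sep = "\t"), p, useBytes = TRUE)
  }, path)
}

#' Read the entity-type map
#'
#' @param path 2-column TSV (entity, type) with type in
#'   `disease`, `gene`, `drug`.
#' @return named character vector: `types[entity] = type`.
#' @export
read_entity_types <- function(path) {
  tsv <- .read_tsv_lines(path)
  parts <- strsplit(tsv$lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0) {
    stopf("malformed type line (expected 2 columns) at line %d of %s",
          tsv$lineno[bad[1]], path)
  }
  m <- do.call(rbind, parts)
  entity_types(stats::setNames(m[, 2], m[, 1]))
}

#' Validate an entity-type map
#'
#' @param types named character vector mapping entity id to one of
#'   `disease`, `gene`, `drug`.
#' @return the validated vector.
#' @export
entity_types <- function(types) {
  allowed <- c("disease", "gene", "drug")
  bad <- setdiff(unique(types), allowed)
  if (length(bad) > 0) stopf("unknown entity type(s): %s", paste(bad, collapse = ", "))
  dup <- names(types)[duplicated(names(types))]
  if (length(dup) > 0) {
    conflict <- vapply(unique(dup), function(e) {
      length(unique(types[names(types) == e])) > 1L
    }, logical(1))
    if (any(conflict)) {
      stopf("entity typed inconsistently: %s",
            paste(unique(dup)[conflict], collapse = ", "))
    }
    types <- types[!duplicated(names(types))]
  }
  types
}

#' Read the father-son bridge map
#'
#' The bridge is the set of (father disease in network 1, son disease in
#' network 2) pairs that connect the two networks; the biased walker may hop
#' across any pair in either direction.
#'
#' @param path 2-column TSV (father, son); `#` comments allowed.
#' @param net1,net2 triples of networks 1 and 2, used to validate that every
#'   father occurs in network 1 and every son in network 2.
#' @return object of class `gcan_bridge` with `pairs` (data frame),
#'   `forward` (father -> character vector of sons) and `reverse`
#'   (son -> fathers) indices.
#' @export
read_bridge <- function(path, net1, net2) {
  tsv <- .read_tsv_lines(path)
  if (length(tsv$lines) == 0) return(bridge_map(character(), character(), net1, net2))
  parts <- strsplit(tsv$lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0) {
    stopf("malformed bridge line (expected 2 columns) at line %d of %s",
          tsv$lineno[bad[1]], path)
  }
  m <- do.call(rbind, parts)
  bridge_map(m[, 1], m[, 2], net1, net2)
}

#' Construct a bridge map in code
#'
#' @param fathers,sons character vectors of equal length; pair `i` links
#'   `fathers[i]` (network 1) to `sons[i]` (network 2).
#' @param net1,net2 triples used for referential validation (optional; pass
#'   `NULL` to skip).
#' @return a `gcan_bridge` object.
#' @export
bridge_map <- function(fathers, sons, net1 = NULL, net2 = NULL) {
  stopifnot(length(fathers) == length(sons))
  pairs <- unique(data.frame(father = as.character(fathers),
                             son = as.character(sons),
                             stringsAsFactors = FALSE))
  rownames(pairs) <- NULL
  if (!is.null(net1) && nrow(pairs) > 0) {
    ents1 <- unique(c(net1$head, net1$tail))
    missing1 <- setdiff(pairs$father, ents1)
    if (length(missing1) > 0) {
      stopf("bridge father entity absent from network 1: %s",
            paste(missing1, collapse = ", "))
    }
  }
  if (!is.null(net2) && nrow(pairs) > 0) {
    ents2 <- unique(c(net2$head, net2$tail))
    missing2 <- setdiff(pairs$son, ents2)
    if (length(missing2) > 0) {
      stopf("bridge son entity absent from network 2: %s",
            paste(missing2, collapse = ", "))
    }
  }
  forward <- if (nrow(pairs) > 0) split(pairs$son, pairs$father) else list()
  reverse <- if (nrow(pairs) > 0) split(pairs$father, pairs$son) else list()
  structure(list(pairs = pairs, forward = forward, reverse = reverse),
            class = "gcan_bridge")
}

#' @export
print.gcan_bridge <- function(x, ...) {
  cat(sprintf("<gcan_bridge> %d father-son pair(s)\n", nrow(x$pairs)))
  invisible(x)
}

.adjacency_from_triples <- function(tr) {
  if (nrow(tr) == 0) return(list())
  # every triple is traversable both ways: head -> tail and tail -> head
  from <- c(tr$head, tr$tail)
  rel <- c(tr$relation, tr$relation)
  to <- c(tr$tail, tr$head)
  adj <- split(data.frame(relation = rel, entity = to, stringsAsFactors = FALSE), from)
  lapply(adj, function(d) { rownames(d) <- NULL; d })
}

#' Build a bridged heterogeneous network
#'
#' Combines the two networks, the entity-type map and the father-son bridge
#' into one object with per-network adjacency. Edges are traversable in both
#' directions during walking.
#'
#' @param triples1,triples2 `gcan_triples` for networks 1 and 2.
#' @param types named character vector from [entity_types()] /
#'   [read_entity_types()]; every entity in either network must be typed.
#' @param bridge a `gcan_bridge`; both members of every pair must be typed
#'   `disease`.
#' @return object of class `bridged_network` with fields `triples1`,
#'   `triples2`, `types`, `bridge`, `adjacency` (list of two adjacency maps)
#'   and `entities` (per-network sorted entity vectors).
#' @export
build_bridged_network <- function(triples1, triples2, types, bridge) {
  types <- entity_types(types)
  ents1 <- sort(unique(c(triples1$head, triples1$tail)), method = "radix")
  ents2 <- sort(unique(c(triples2$head, triples2$tail)), method = "radix")
  untyped <- setdiff(c(ents1, ents2), names(types))
  if (length(untyped) > 0) {
    stopf("untyped entit%s: %s", if (length(untyped) == 1) "y" else "ies",
          paste(sort(untyped), collapse = ", "))
  }
  if (nrow(bridge$pairs) > 0) {
    bd <- unique(c(bridge$pairs$father, bridge$pairs$son))
    notdis <- bd[types[bd] != "disease"]
    if (length(notdis) > 0) {
      stopf("bridge entity not typed disease: %s", paste(notdis, collapse = ", "))
    }
    if (!all(bridge$pairs$father %in% ents1)) {
      stopf("bridge father absent from network 1: %s",
            paste(setdiff(bridge$pairs$father, ents1), collapse = ", "))
    }
    if (!all(bridge$pairs$son %in% ents2)) {
      stopf("bridge son absent from network 2: %s",
            paste(setdiff(bridge$pairs$son, ents2), collapse = ", "))
    }
  }
  net <- structure(list(
    triples1 = triples1, triples2 = triples2,
    types = types, bridge = bridge,
    adjacency = list(.adjacency_from_triples(triples1),
                     .adjacency_from_triples(triples2)),
    entities = list(ents1, ents2)
  ), class = "bridged_network")
  gcan_log("debug", "bridged network: %d + %d triples, %d + %d entities, %d bridge pairs",
           nrow(triples1), nrow(triples2), length(ents1), length(ents2),
           nrow(bridge$pairs))
  net
}

#' @export
print.bridged_network <- function(x, ...) {
  rels <- unique(c(x$triples1$relation, x$triples2$relation))
  cat(sprintf(paste0("<bridged_network>\n  network 1: %d triples, %d entities\n",
                     "  network 2: %d triples, %d entities\n",
                     "  relations: %d distinct; bridge pairs: %d\n"),
              nrow(x$triples1), length(x$entities[[1]]),
              nrow(x$triples2), length(x$entities[[2]]),
              length(rels), nrow(x$bridge$pairs)))
  invisible(x)
}

#' Build the token vocabulary
#'
#' Tokens are all entities of both networks, all relation labels, and the
#' reserved bridge-relation token. Indices are contiguous from 0. When a walk
#' corpus is supplied, token frequencies are counts over the corpus (these
#' feed the frequency-proportional noise distribution of the
#' negative-sampling objective); otherwise all frequencies are 1.
#'
#' @param network a `bridged_network`.
#' @param corpus optional `gcan_corpus` (list of walks) for frequencies.
#' @param bridge_token the reserved cross-network relation token.
#' @return object of class `gcan_vocabulary`: data frame `tokens` with
#'   columns `token`, `index` (0-based), `kind`
#'   (`entity`/`relation`/`bridge-relation`), `freq`, plus a fast `token ->
#'   index` lookup.
#' @export
build_vocabulary <- function(network, corpus = NULL,
                             bridge_token = GCAN_BRIDGE_TOKEN) {
  ents <- sort(unique(c(network$entities[[1]], network$entities[[2]])), method = "radix")
  rels <- sort(unique(c(network$triples1$relation, network$triples2$relation)), method = "radix")
  if (bridge_token %in% c(ents, rels)) {
    stopf("bridge token '%s' collides with a network token", bridge_token)
  }
  tok <- c(ents, rels, bridge_token)
  kind <- c(rep("entity", length(ents)), rep("relation", length(rels)),
            "bridge-relation")
  freq <- rep(1, length(tok))
  if (!is.null(corpus)) {
    counts <- table(unlist(corpus, use.names = FALSE))
    freq <- rep(0, length(tok))
    hit <- match(names(counts), tok)
    if (anyNA(hit)) {
      stopf("corpus token absent from network vocabulary: %s",
            paste(names(counts)[is.na(hit)][1], collapse = ", "))
    }
    freq[hit] <- as.numeric(counts)
  }
  tokens <- data.frame(token = tok, index = seq_along(tok) - 1L, kind = kind,
                       freq = freq, stringsAsFactors = FALSE)
  lookup <- stats::setNames(tokens$index, tokens$token)
  structure(list(tokens = tokens, lookup = lookup,
                 bridge_token = bridge_token,
                 size = nrow(tokens)),
            class = "gcan_vocabulary")
}

#' @export
print.gcan_vocabulary <- function(x, ...) {
  cat(sprintf("<gcan_vocabulary> %d tokens (%d entities, %d relations + bridge)\n",
              x$size, sum(x$tokens$kind == "entity"),
              sum(x$tokens$kind == "relation")))
  invisible(x)
}

#' Map tokens to 0-based vocabulary indices
#' @param vocab a `gcan_vocabulary`.
#' @param tokens character vector.
#' @return integer vector of indices; errors on unknown tokens.
#' @export
vocab_index <- function(vocab, tokens) {
  idx <- vocab$lookup[tokens]
  if (anyNA(idx)) stopf("token not in vocabulary: %s", tokens[is.na(idx)][1])
  unname(idx)
}

#' Map 0-based vocabulary indices back to tokens
#' @param vocab a `gcan_vocabulary`.
#' @param index integer vector of 0-based indices.
#' @return character vector of tokens.
#' @export
vocab_token <- function(vocab, index) {
  if (any(index < 0L | index >= vocab$size)) stopf("vocabulary index out of range")
  vocab$tokens$token[index + 1L]
}

#' List entities of one type across both networks
#' @param network a `bridged_network`.
#' @param type `"disease"`, `"gene"` or `"drug"`.
#' @return sorted character vector of entity ids.
#' @export
entities_of_type <- function(network, type) {
  ents <- unique(c(network$entities[[1]], network$entities[[2]]))
  sort(ents[network$types[ents] == type], method = "radix")
}
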