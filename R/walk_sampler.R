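# Father-son-biased random-walk sampling over a bridged network.
#
# At every step the walker sees two candidate classes: cross-network
# candidates (the bridge partners of the current disease node) and
# within-network candidates (graph neighbors). With probability alpha the
# step is a cross-network hop to a uniformly chosen bridge partner, with
# probability 1 - alpha a uniformly chosen within-network move. An empty
# class donates its mass to the other. Cross steps emit a reserved bridge
# relation token and flip the current network id.

#' Walk-sampling configuration
#'
#' @param alpha probability mass of the cross-network (father-son) step class,
#'   in `[0, 1]`. The value used in the original experiments is unreported;
#'   0.5 is the package default and should be treated as tunable.
#' @param depth_hops walk depth counted in relation traversals; a walk of
#'   `depth_hops` hops has `2 * depth_hops + 1` tokens. Default 15, the depth
#'   at which ranking accuracy was observed to plateau in a 5-21 hop sweep.
#' @param walks_per_entity walks started from every entity of both networks.
#' @param seed integer seed controlling the whole corpus.
#' @param bridge_token relation token emitted for cross-network steps.
#' @return object of class `walk_config`.
#' @export
walk_config <- function(alpha = 0.5, depth_hops = 15L, walks_per_entity = 10L,
                        seed = 1L, bridge_token = GCAN_BRIDGE_TOKEN) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1) {
    stopf("alpha must be a single number in [0, 1]")
  }
  depth_hops <- as.integer(depth_hops)
  walks_per_entity <- as.integer(walks_per_entity)
  if (depth_hops < 1L) stopf("depth_hops must be >= 1")
  if (walks_per_entity < 1L) stopf("walks_per_entity must be >= 1")
  structure(list(alpha = alpha, depth_hops = depth_hops,
                 walks_per_entity = walks_per_entity, seed = as.integer(seed),
                 bridge_token = bridge_token),
            class = "walk_config")
}

#' Candidate next-step sets at an entity
#'
#' @param network a `bridged_network`.
#' @param entity current entity id.
#' @param network_id network the walker is currently in (1 or 2).
#' @return list with `cross` (character vector of bridge partners in the
#'   other network) and `within` (data frame `relation`, `entity` of
#'   neighbors in the current network).
#' @export
candidate_sets <- function(network, entity, network_id) {
  network_id <- as.integer(network_id)
  if (!entity %in% network$entities[[network_id]]) {
    stopf("entity '%s' not present in network %d", entity, network_id)
  }
  idx <- if (network_id == 1L) network$bridge$forward else network$bridge$reverse
  cross <- idx[[entity]] %||% character()
  within <- network$adjacency[[network_id]][[entity]] %||%
    data.frame(relation = character(), entity = character(),
               stringsAsFactors = FALSE)
  list(cross = cross, within = within)
}

#' Single-step transition distribution of the biased walk
#'
#' If both candidate classes are nonempty, the cross class carries total mass
#' `alpha` and the within class `1 - alpha`, each split uniformly over its
#' members. If one class is empty its mass goes entirely to the other. If
#' both are empty the entity is a dead end and `NULL` is returned (callers
#' truncate the walk).
#'
#' @param cross character vector of cross-network candidates.
#' @param within data frame (`relation`, `entity`) of within-network
#'   candidates.
#' @param alpha cross-class probability mass in `[0, 1]`.
#' @return data frame with columns `entity`, `relation` (`NA` for cross
#'   candidates), `class` (`"cross"`/`"within"`), `prob`; or `NULL` at a dead
#'   end.
#' @export
step_distribution <- function(cross, within, alpha) {
  n_c <- length(cross)
  n_w <- nrow(within)
  if (n_c == 0 && n_w == 0) return(NULL)
  mass_c <- if (n_c == 0) 0 else if (n_w == 0) 1 else alpha
  mass_w <- 1 - mass_c
  out <- data.frame(
    entity = c(cross, within$entity),
    relation = c(rep(NA_character_, n_c), within$relation),
    class = c(rep("cross", n_c), rep("within", n_w)),
    prob = c(rep(if (n_c > 0) mass_c / n_c else 0, n_c),
             rep(if (n_w > 0) mass_w / n_w else 0, n_w)),
    stringsAsFactors = FALSE
  )
  out
}

#' Sample one biased walk
#'
#' Produces an alternating entity/relation token sequence starting at
#' `start_entity`. Cross-network steps emit the bridge token as their
#' relation and flip the current network. Dead ends truncate the walk.
#' Randomness is taken from the calling R RNG state.
#'
#' @param network a `bridged_network`.
#' @param start_entity entity id present in network `start_network_id`.
#' @param config a `walk_config`.
#' @param start_network_id network containing the start entity (default: 1 if
#'   present there, else 2).
#' @return object of class `walk_path`: list with `tokens` (character,
#'   odd length) and `networks` (integer network id per entity position).
#' @export
sample_walk <- function(network, start_entity, config,
                        start_network_id = NULL) {
  if (is.null(start_network_id)) {
    start_network_id <- if (start_entity %in% network$entities[[1]]) 1L else 2L
  }
  cur <- start_entity
  cur_net <- as.integer(start_network_id)
  tokens <- character(2L * config$depth_hops + 1L)
  nets <- integer(config$depth_hops + 1L)
  tokens[1L] <- cur
  nets[1L] <- cur_net
  n_tok <- 1L
  n_ent <- 1L
  for (hop in seq_len(config$depth_hops)) {
    cand <- candidate_sets(network, cur, cur_net)
    dist <- step_distribution(cand$cross, cand$within, config$alpha)
    if (is.null(dist)) break
    pick <- if (nrow(dist) == 1L) 1L else {
      sample.int(nrow(dist), 1L, prob = dist$prob)
    }
    if (dist$class[pick] == "cross") {
      rel <- config$bridge_token
      cur_net <- 3L - cur_net
    } else {
      rel <- dist$relation[pick]
    }
    cur <- dist$entity[pick]
    tokens[n_tok + 1L] <- rel
    tokens[n_tok + 2L] <- cur
    n_tok <- n_tok + 2L
    n_ent <- n_ent + 1L
    nets[n_ent] <- cur_net
  }
  structure(list(tokens = tokens[seq_len(n_tok)],
                 networks = nets[seq_len(n_ent)]),
            class = "walk_path")
}

#' @export
print.walk_path <- function(x, ...) {
  cat(sprintf("<walk_path> %d tokens (%d hops): %s\n",
              length(x$tokens), (length(x$tokens) - 1L) %/% 2L,
              paste(x$tokens, collapse = " ")))
  invisible(x)
}

#' Sample a walk corpus over the whole network
#'
#' Starts `walks_per_entity` walks from every entity of both networks, in
#' sorted entity order, under `config$seed`; the same seed always yields the
#' identical corpus. Walks that die immediately (isolated start, a single
#' token) are dropped: they carry no prediction targets.
#'
#' @param network a `bridged_network`.
#' @param config a `walk_config`.
#' @return object of class `gcan_corpus`: list of character token vectors.
#' @export
sample_corpus <- function(network, config) {
  starts <- rbind(
    data.frame(entity = network$entities[[1]], net = 1L, stringsAsFactors = FALSE),
    data.frame(entity = network$entities[[2]], net = 2L, stringsAsFactors = FALSE)
  )
  if (nrow(starts) == 0) stopf("network has no entities")
  walks <- vector("list", nrow(starts) * config$walks_per_entity)
  k <- 0L
  with_seed(config$seed, {
    for (i in seq_len(nrow(starts))) {
      for (w in seq_len(config$walks_per_entity)) {
        p <- sample_walk(network, starts$entity[i], config,
                         start_network_id = starts$net[i])
        if (length(p$tokens) >= 3L) {
          k <- k + 1L
          walks[[k]] <- p$tokens
        }
      }
    }
  })
  structure(walks[seq_len(k)], class = "gcan_corpus")
}

#' Fraction of cross-network steps in a corpus
#'
#' Diagnostic for the bias parameter: the share of relation tokens that are
#' the bridge token. When every visited entity offers both candidate classes
#' this converges to `alpha`.
#'
#' @param corpus a `gcan_corpus`.
#' @param bridge_token the bridge relation token.
#' @return fraction in `[0, 1]`.
#' @export
cross_step_fraction <- function(corpus, bridge_token = GCAN_BRIDGE_TOKEN) {
  if (length(corpus) == 0) stopf("corpus is empty")
  n_rel <- 0L
  n_cross <- 0L
  for (tok in corpus) {
    rels <- tok[seq_along(tok) %% 2L == 0L]
    n_rel <- n_rel + length(rels)
    n_cross <- n_cross + sum(rels == bridge_token)
  }
  if (n_rel == 0L) stopf("corpus contains no relation tokens")
  n_cross / n_rel
}

#' Write a corpus to disk (one walk per line, space-separated)
#' @param corpus a `gcan_corpus`.
#' @param path destination path (written atomically).
#' @export
write_corpus <- function(corpus, path) {
  atomic_write(function(p) {
    writeLines(vapply(corpus, paste, character(1), collapse = " "), p,
               useBytes = TRUE)
  }, path)
}

#' Read a corpus written by [write_corpus()]
#' @param path corpus file path.
#' @return a `gcan_corpus`.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  structure(strsplit(lines, " ", fixed = TRUE), class = "gcan_corpus")
}
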