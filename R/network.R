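# Directed network construction, Metropolis rewiring and correlation statistics.

new_lif_network <- function(n, from, to, delay_ms) {
  from <- as.integer(from); to <- as.integer(to)
  structure(list(n = as.integer(n), from = from, to = to,
                 delay_ms = as.numeric(delay_ms),
                 in_degree = tabulate(to, nbins = n),
                 out_degree = tabulate(from, nbins = n)),
            class = "lif_network")
}

#' @export
print.lif_network <- function(x, ...) {
  cat(sprintf("Directed LIF network: %d nodes, %d edges\n", x$n, length(x$from)))
  cat(sprintf("  in-degree range [%d, %d], delays in [%.2f, %.2f] ms\n",
              min(x$in_degree), max(x$in_degree),
              min(x$delay_ms), max(x$delay_ms)))
  invisible(x)
}

validate_network <- function(net) {
  stopifnot(inherits(net, "lif_network"))
  if (any(net$from == net$to)) stop("network contains self-loops")
  if (anyDuplicated(net$from * as.double(net$n) + net$to))
    stop("network contains duplicate edges")
  invisible(net)
}

#' Directed configuration model
#'
#' Builds a random directed graph realizing the given target in- and
#' out-degree sequences by uniform stub matching (delegated to
#' \code{igraph::sample_degseq}).  Self-loops and multiple edges are removed
#' afterwards, so realized degrees can fall slightly below their targets;
#' degree classes downstream are always recomputed from the realized graph.
#' Synaptic delays are assigned per edge, uniformly at random on
#' \code{delay_range} (ms).
#'
#' @param degree_sequence integer vector of target in-degrees; with the
#'   default \code{out_degree = degree_sequence} every node has equal in- and
#'   out-degree.
#' @param out_degree target out-degree sequence (same stub total required).
#' @param delay_range length-2 numeric, delay bounds in ms.
#' @param seed optional integer seed.
#' @return A \code{"lif_network"}: list with \code{n}, \code{from}, \code{to}
#'   (1-based node ids), \code{delay_ms}, \code{in_degree}, \code{out_degree}.
#' @export
configuration_model <- function(degree_sequence, out_degree = degree_sequence,
                                delay_range = c(0, 6), seed = NULL) {
  if (length(degree_sequence) == 0L) stop("empty degree sequence")
  if (sum(degree_sequence) != sum(out_degree))
    stop("in- and out-stub totals differ")
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_degseq(out.deg = out_degree, in.deg = degree_sequence,
                             method = "configuration")
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  el <- igraph::as_edgelist(g, names = FALSE)
  new_lif_network(length(degree_sequence), el[, 1L], el[, 2L],
                  runif(nrow(el), delay_range[1L], delay_range[2L]))
}

#' Metropolis rewiring of in-degree correlations
#'
#' Repeatedly picks two random directed links and proposes to swap their
#' targets, which preserves every node's in- and out-degree.  With probability
#' \code{g} the swap is accepted only if it moves the link-end in-degree
#' product sum \eqn{k_i m_i + k_j m_j} in the requested direction (up for
#' \code{mode = "assortative"}, down for \code{"disassortative"}); with
#' probability \code{1 - g} it is accepted unconditionally, which erodes
#' existing correlations.  Proposals that would create a self-loop or
#' duplicate edge are rejected but still count against \code{n_attempts}.
#'
#' @param network a \code{"lif_network"}.
#' @param mode \code{"assortative"} or \code{"disassortative"}.
#' @param g acceptance bias in [0, 1]; 1 = strictly correlation-increasing.
#' @param n_attempts number of swap attempts (default 100 per edge).
#' @param seed optional integer seed.
#' @return The rewired \code{"lif_network"}, with attribute
#'   \code{"accepted_swaps"}.
#' @export
metropolis_rewire <- function(network, mode = c("assortative", "disassortative"),
                              g = 1, n_attempts = NULL, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(network, "lif_network"))
  E <- length(network$from)
  if (E < 2L) stop("rewiring needs at least 2 edges")
  if (g < 0 || g > 1) stop("'g' must be in [0, 1]")
  if (is.null(n_attempts)) n_attempts <- 100 * E
  if (!is.null(seed)) set.seed(seed)
  res <- rewire_cpp(network$from - 1L, network$to - 1L, network$in_degree,
                    network$n, if (mode == "assortative") 1L else -1L,
                    g, as.numeric(n_attempts))
  out <- new_lif_network(network$n, network$from, res$to + 1L, network$delay_ms)
  attr(out, "accepted_swaps") <- res$accepted
  out
}

#' Rewire until the Pearson coefficient plateaus
#'
#' Runs maximal (\code{g = 1}) Metropolis rewiring in blocks of
#' \code{block_attempts} and stops when the Pearson in-degree correlation
#' changes by less than \code{p_tol} between consecutive blocks (or when
#' \code{max_attempts} is exhausted).
#'
#' @inheritParams metropolis_rewire
#' @param block_attempts attempts per block (default 10 per edge).
#' @param p_tol plateau tolerance on the Pearson coefficient.
#' @param max_attempts overall attempt budget (default 500 per edge).
#' @return list with \code{network}, \code{p} (Pearson trace per block) and
#'   \code{attempts}.
#' @export
rewire_to_plateau <- function(network, mode = c("assortative", "disassortative"),
                              g = 1, block_attempts = NULL, p_tol = 1e-3,
                              max_attempts = NULL, seed = NULL) {
  mode <- match.arg(mode)
  E <- length(network$from)
  if (is.null(block_attempts)) block_attempts <- 10 * E
  if (is.null(max_attempts)) max_attempts <- 500 * E
  if (!is.null(seed)) set.seed(seed)
  p_trace <- pearson_in_degree_correlation(network)$p
  used <- 0
  while (used < max_attempts) {
    network <- metropolis_rewire(network, mode, g = g,
                                 n_attempts = block_attempts)
    used <- used + block_attempts
    p_trace <- c(p_trace, pearson_in_degree_correlation(network)$p)
    np <- length(p_trace)
    if (abs(p_trace[np] - p_trace[np - 1L]) < p_tol) break
  }
  list(network = network, p = p_trace, attempts = used)
}

#' Rewire towards a target Pearson coefficient
#'
#' Places a network at a prescribed assortativity level: maximal (\code{g = 1})
#' Metropolis rewiring is applied in adaptively sized blocks, assortative while
#' the Pearson coefficient is below \code{p_target} and disassortative while it
#' is above, until \eqn{|p - p_{target}| \le} \code{p_tol}.  Early blocks are
#' kept small because the chain moves \code{p} quickly on an uncorrelated
#' network.
#'
#' @inheritParams rewire_to_plateau
#' @param p_target desired Pearson coefficient.
#' @param p_tol acceptable distance from the target.
#' @return list with \code{network} and \code{p_achieved}.  If the target is
#'   unreachable within \code{max_attempts} (or the chain saturates short of
#'   it) the achieved value is returned with a warning.
#' @export
rewire_to_assortativity <- function(network, p_target, p_tol = 0.01,
                                    max_attempts = NULL, seed = NULL) {
  E <- length(network$from)
  if (is.null(max_attempts)) max_attempts <- 800 * E
  if (!is.null(seed)) set.seed(seed)
  p <- pearson_in_degree_correlation(network)$p
  used <- 0
  stalled <- 0L
  while (abs(p - p_target) > p_tol && used < max_attempts) {
    gap <- p_target - p
    block <- ceiling(E * max(0.05, min(25, 2 * abs(gap))))
    network <- metropolis_rewire(network,
                                 if (gap > 0) "assortative" else "disassortative",
                                 g = 1, n_attempts = block)
    used <- used + block
    p_new <- pearson_in_degree_correlation(network)$p
    stalled <- if (abs(p_new - p) < p_tol / 10) stalled + 1L else 0L
    p <- p_new
    if (stalled >= 5L) break  # saturated short of the target
  }
  if (abs(p - p_target) > p_tol)
    warning(sprintf("target p = %.3f unreachable; achieved p = %.3f",
                    p_target, p))
  list(network = network, p_achieved = p)
}

#' Pearson in-degree correlation of a directed network
#'
#' Quantifies in-degree assortativity: the correlation between the in-degrees
#' found at the origin and at the target of a randomly chosen directed link.
#' The primary coefficient \code{p} normalizes the link-end covariance
#' \eqn{\sum_{kk'} k k' e_{kk'} - (\sum_k k Q^{in}_k)^2} by the variance
#' \eqn{\sigma_{in}^2} of the excess in-degree distribution
#' \eqn{Q^{in}_k = (k+1) P(k+1) / \sum_k k P(k)}.  Because \eqn{Q^{in}}
#' derives from the node degree distribution rather than from the link sample,
#' \code{p} can exceed 1 slightly on finite graphs; the plain sample Pearson
#' correlation over link ends is therefore also returned as \code{p_edge} (a
#' diagnostic, not a substitute).
#'
#' @param network a \code{"lif_network"} with at least one edge.
#' @return An object of class \code{"correlation_stats"}: list with \code{p},
#'   \code{p_edge}, \code{e_kk} (data frame \code{k}, \code{k_prime},
#'   \code{prob} of link-end in-degree pairs), \code{Q_in} (data frame
#'   \code{k}, \code{prob}) and \code{sigma_in_sq}.
#' @export
pearson_in_degree_correlation <- function(network) {
  stopifnot(inherits(network, "lif_network"))
  E <- length(network$from)
  if (E < 1L) stop("network has no edges")
  indeg <- network$in_degree
  k_tgt <- indeg[network$to]     # link leads INTO in-degree k ...
  k_org <- indeg[network$from]   # ... OUT OF in-degree k'
  # node in-degree distribution P(k)
  ktab <- table(indeg)
  kv <- as.numeric(names(ktab))
  pk <- as.numeric(ktab) / network$n
  kbar <- sum(kv * pk)
  # excess in-degree distribution Q_k = (k+1) P(k+1) / sum k P(k)
  qk <- (kv * pk) / kbar            # mass sits at degree k - 1
  q_support <- kv - 1
  mean_q <- sum(q_support * qk)
  sigma_in_sq <- sum(q_support^2 * qk) - mean_q^2
  if (sigma_in_sq <= 0)
    stop("sigma_in_sq = 0: link-end in-degrees are regular, p is undefined")
  p <- (mean(as.numeric(k_org) * k_tgt) - mean_q^2) / sigma_in_sq
  # plain sample Pearson correlation over link ends (diagnostic)
  p_edge <- suppressWarnings(stats::cor(k_org, k_tgt))
  ekk <- as.data.frame(table(k = k_tgt, k_prime = k_org),
                       stringsAsFactors = FALSE)
  ekk <- ekk[ekk$Freq > 0, ]
  e_kk <- data.frame(k = as.integer(ekk$k), k_prime = as.integer(ekk$k_prime),
                     prob = ekk$Freq / E)
  structure(list(p = p, p_edge = p_edge, e_kk = e_kk,
                 Q_in = data.frame(k = q_support, prob = qk),
                 sigma_in_sq = sigma_in_sq),
            class = "correlation_stats")
}

#' @export
print.correlation_stats <- function(x, ...) {
  cat(sprintf("In-degree correlation: p = %.4f (excess-distribution normalization)\n", x$p))
  cat(sprintf("                  p_edge = %.4f (sample Pearson over link ends)\n", x$p_edge))
  invisible(x)
}

#' Write / read an edge-list file
#'
#' Plain TSV with comment header lines starting with \code{#} and columns
#' \code{source}, \code{target}, \code{delay_ms}; node ids are 1-based.
#'
#' @param network a \code{"lif_network"}.
#' @param path file path.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "lif_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# lifnet edge list, n_nodes=%d", network$n),
               "# source\ttarget\tdelay_ms"), con)
  write.table(data.frame(network$from, network$to,
                         format(network$delay_ms, digits = 10)),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @param n_nodes node count; if \code{NULL}, taken from the \code{n_nodes=}
#'   header comment or the maximum node id.
#' @export
read_edge_list <- function(path, n_nodes = NULL) {
  hdr <- readLines(path, n = 5L)
  hdr <- hdr[startsWith(hdr, "#")]
  if (is.null(n_nodes)) {
    m <- regmatches(hdr, regexpr("n_nodes=[0-9]+", hdr))
    n_nodes <- if (length(m)) as.integer(sub("n_nodes=", "", m[[1L]])) else NA
  }
  df <- read.table(path, sep = "\t", comment.char = "#",
                   col.names = c("source", "target", "delay_ms"))
  if (is.na(n_nodes) || is.null(n_nodes))
    n_nodes <- max(df$source, df$target)
  new_lif_network(n_nodes, df$source, df$target, df$delay_ms)
}
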