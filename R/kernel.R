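# Joint degree distributions N_kk' and connection kernels f(k, k').

new_connection_kernel <- function(degrees, N, weights = NULL,
                                  class_sizes = NULL) {
  degrees <- as.integer(degrees)
  f <- N / degrees  # row k of N sums to k
  dimnames(N) <- dimnames(f) <- list(k = degrees, k_prime = degrees)
  structure(list(degrees = degrees, f = f, N = N, weights = weights,
                 class_sizes = class_sizes),
            class = "connection_kernel")
}

#' @export
print.connection_kernel <- function(x, ...) {
  cat(sprintf("Connection kernel on %d in-degree classes [%d, %d]\n",
              length(x$degrees), min(x$degrees), max(x$degrees)))
  rs <- rowSums(x$f)
  cat(sprintf("  max |row sum of f - 1| = %.2e\n", max(abs(rs - 1))))
  invisible(x)
}

#' Sample the joint degree distribution of a network
#'
#' Estimates \eqn{N_{kk'}}, the mean number of in-degree-\eqn{k'} neurons that
#' synapse into an in-degree-\eqn{k} neuron, by tallying the directed links of
#' the realized graph: \eqn{N_{kk'} = k E_{kk'} / \sum_{k''} E_{kk''}}, where
#' \eqn{E_{kk'}} counts links from \eqn{k'}-class into \eqn{k}-class nodes.
#' The kernel \eqn{f(k,k') = N_{kk'} / k} gives the probability that a random
#' input of a \eqn{k}-neuron originates from a \eqn{k'}-neuron; every row of
#' \eqn{f} sums to one.
#'
#' @param network a \code{"lif_network"}.
#' @return A \code{"connection_kernel"} whose \code{weights} are the empirical
#'   class proportions (used downstream to average over populations) and whose
#'   \code{class_sizes} are the node counts per in-degree class.
#' @export
sample_joint_degree <- function(network) {
  stopifnot(inherits(network, "lif_network"))
  indeg <- network$in_degree
  keep <- indeg > 0
  if (!all(keep))
    warning(sum(!keep), " node(s) with zero in-degree excluded from the kernel")
  degrees <- sort(unique(indeg[keep]))
  idx <- match(indeg, degrees)
  m <- length(degrees)
  kt <- idx[network$to]; ko <- idx[network$from]
  E <- matrix(0, m, m)
  cnt <- table(factor(kt, levels = seq_len(m)), factor(ko, levels = seq_len(m)))
  E[] <- as.numeric(cnt)
  row_tot <- rowSums(E)
  if (any(row_tot == 0))
    stop("in-degree class with zero incoming links: f row undefined")
  N <- degrees * E / row_tot
  sizes <- as.numeric(table(factor(indeg[keep], levels = degrees)))
  new_connection_kernel(degrees, N, weights = sizes / sum(sizes),
                        class_sizes = sizes)
}

#' Closed-form connection kernels
#'
#' Analytic kernels \eqn{f(k,k')} for the limiting network ensembles, on the
#' support of \code{dist}:
#' \describe{
#'   \item{independent_inout}{in- and out-degrees drawn independently:
#'     \eqn{f(k,k') = P(k')}, independent of \eqn{k}.}
#'   \item{uncorrelated_equal_inout}{equal in/out degree per node, links
#'     uncorrelated: \eqn{f(k,k') = k' P(k') / \langle k \rangle}.}
#'   \item{assortative_delta}{maximally assortative limit: the network
#'     segregates into same-degree subnetworks, \eqn{f(k,k') = \delta(k,k')}.}
#'   \item{disassortative_delta}{maximally disassortative limit: class
#'     \eqn{k} is fed by the complementary class
#'     \eqn{k' \approx k_{min} k_{max} / k}; the generally non-integer partner
#'     degree is mapped to the nearest degree in the support, ties toward the
#'     smaller degree.}
#' }
#'
#' @param dist a \code{"degree_dist"}.
#' @param kind kernel type, see Details.
#' @return A \code{"connection_kernel"} with \code{weights = dist$pmf}.
#' @export
analytic_kernel <- function(dist, kind = c("uncorrelated_equal_inout",
                                           "independent_inout",
                                           "assortative_delta",
                                           "disassortative_delta")) {
  stopifnot(inherits(dist, "degree_dist"))
  kind <- match.arg(kind)
  k <- dist$k
  m <- length(k)
  f <- switch(kind,
    independent_inout = matrix(dist$pmf, m, m, byrow = TRUE),
    uncorrelated_equal_inout = {
      kbar <- sum(k * dist$pmf)
      matrix(k * dist$pmf / kbar, m, m, byrow = TRUE)
    },
    assortative_delta = diag(m),
    disassortative_delta = {
      partner <- vapply(k, function(kk) {
        target <- dist$k_min * dist$k_max / kk
        d <- abs(k - target)
        cand <- which(d == min(d))
        k[cand[which.min(k[cand])]]  # tie toward the smaller degree
      }, 0L)
      fm <- matrix(0, m, m)
      fm[cbind(seq_len(m), match(partner, k))] <- 1
      fm
    })
  new_connection_kernel(k, k * f, weights = dist$pmf)
}

#' Write / read a joint-degree-distribution file
#'
#' CSV matrix of counts \eqn{N_{kk'}} whose first row and first column hold
#' the degree labels.
#'
#' @param kernel a \code{"connection_kernel"}.
#' @param path file path.
#' @export
write_kernel <- function(kernel, path) {
  stopifnot(inherits(kernel, "connection_kernel"))
  m <- rbind(c(NA, kernel$degrees), cbind(kernel$degrees, kernel$N))
  write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE,
              na = "")
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  m <- as.matrix(read.table(path, sep = ",", header = FALSE))
  degrees <- as.integer(m[1L, -1L])
  new_connection_kernel(degrees, unname(m[-1L, -1L, drop = FALSE]))
}
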