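#' Directed clustering coefficient
#'
#' Counts directed triplets in the style of the total clustering
#' coefficient for directed graphs: for each node, the number of
#' triangles closed in any edge-direction combination,
#' `t_i = ((A + A')^3)_ii / 2`, against the number of triplets that could
#' form, `d_i^tot (d_i^tot - 1) - 2 d_i^bidir`. The `"global"` variant
#' (used for the small-world index) is the ratio of total closed to total
#' possible triplets; `"local"` is the mean of per-node coefficients over
#' nodes with at least one possible triplet.
#'
#' @param a square 0/1 (or logical) adjacency matrix, no self-loops.
#' @param type `"global"` or `"local"`.
#' @return clustering coefficient in `[0, 1]`.
#' @export
directed_clustering <- function(a, type = c("global", "local")) {
  type <- match.arg(type)
  a <- (a != 0) * 1
  diag(a) <- 0
  s <- a + t(a)
  tri <- diag(s %*% s %*% s) / 2
  d_tot <- rowSums(a) + colSums(a)
  d_bi <- diag(a %*% a)
  denom <- d_tot * (d_tot - 1) - 2 * d_bi
  if (type == "global") {
    if (sum(denom) == 0) return(NA_real_)
    sum(tri) / sum(denom)
  } else {
    ok <- denom > 0
    if (!any(ok)) return(NA_real_)
    mean(tri[ok] / denom[ok])
  }
}

#' Mean shortest directed path length
#'
#' Mean over all ordered pairs of nodes of the shortest directed path
#' length (breadth-first search from every node). If some pairs are
#' unreachable, the mean is taken over reachable pairs and the
#' unreachable fraction is reported.
#'
#' @param a adjacency matrix (directed, no self-loops).
#' @return list with `L` (mean path length), `frac_unreachable`.
#' @export
mean_path_length <- function(a) {
  a <- (a != 0)
  diag(a) <- FALSE
  n <- nrow(a)
  adj <- lapply(seq_len(n), function(i) which(a[i, ]))
  res <- bfs_mean_path_cpp(adj, n)
  list(L = res[1L], frac_unreachable = 1 - res[2L] / res[3L])
}

#' Small-world index of a directed graph
#'
#' `SWI = (L - Ll) / (Lr - Ll) * (C - Cr) / (Cl - Cr)`, locating the
#' graph's mean path length `L` between the lattice (`Ll`) and random
#' (`Lr`) references and its clustering `C` between the random (`Cr`)
#' and lattice (`Cl`) references. For a directed graph of size `n`, mean
#' degree `k` and connection probability `p` the closed-form references
#' are `Cr = p`, `Lr = (ln n - gamma) / ln k + 0.5` (gamma the
#' Euler-Mascheroni constant), `Cl = 3 (k - 2) / (4 (k - 1))`, and
#' `Ll = n / (2 k) + 0.5`. An index near 1 marks lattice-like clustering
#' combined with random-like path lengths.
#'
#' @param n number of nodes.
#' @param k mean degree.
#' @param p connection probability.
#' @param c_coef observed clustering coefficient.
#' @param l_path observed mean path length.
#' @return list with `swi` and the four reference values.
#' @export
swi <- function(n, k, p, c_coef, l_path) {
  if (k <= 2) stop("small-world references require mean degree above 2")
  gamma_em <- -digamma(1)   # Euler-Mascheroni constant 0.5772...
  c_r <- p
  l_r <- (log(n) - gamma_em) / log(k) + 0.5
  c_l <- 3 * (k - 2) / (4 * (k - 1))
  l_l <- n / (2 * k) + 0.5
  if (l_r == l_l || c_l == c_r)
    stop("degenerate reference graphs: lattice and random coincide")
  value <- (l_path - l_l) / (l_r - l_l) * (c_coef - c_r) / (c_l - c_r)
  list(swi = value, c_r = c_r, l_r = l_r, c_l = c_l, l_l = l_l)
}

#' Small-world summary of a network's E-to-E graph
#'
#' @param network a [build_network()] object (or an adjacency matrix plus
#'   `p`).
#' @param p connection probability for the random reference; defaults to
#'   the configured global E-to-E probability.
#' @return class `graph_summary`: `C` (global directed clustering),
#'   `C_local`, `L`, `frac_unreachable`, `k` (empirical mean out-degree),
#'   references, and `swi`.
#' @export
graph_summary <- function(network, p = NULL) {
  if (inherits(network, "clustered_network")) {
    a <- network$conn$ee
    if (is.null(p)) p <- network$config$network$p_ee
  } else {
    a <- network
    if (is.null(p)) stop("supply the connection probability p")
  }
  a <- (a != 0) * 1
  diag(a) <- 0
  k <- mean(rowSums(a))
  c_glob <- directed_clustering(a, "global")
  c_loc <- directed_clustering(a, "local")
  pl <- mean_path_length(a)
  refs <- swi(nrow(a), k, p, c_glob, pl$L)
  structure(list(C = c_glob, C_local = c_loc, L = pl$L,
                 frac_unreachable = pl$frac_unreachable, k = k, p = p,
                 c_r = refs$c_r, l_r = refs$l_r, c_l = refs$c_l,
                 l_l = refs$l_l, swi = refs$swi),
            class = "graph_summary")
}

#' @export
print.graph_summary <- function(x, ...) {
  cat(sprintf("Directed graph summary: n k = %.1f, C = %.3f (refs %.3f-%.3f), L = %.2f (refs %.2f-%.2f), SWI = %.3f\n",
              x$k, x$C, x$c_r, x$c_l, x$L, x$l_r, x$l_l, x$swi))
  if (x$frac_unreachable > 0)
    cat(sprintf("  note: %.2f%% of ordered pairs unreachable\n",
                100 * x$frac_unreachable))
  invisible(x)
}
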