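#' Signed-network Louvain modularity
#'
#' Community detection on a signed, weighted, undirected FC matrix using the
#' asymmetric signed quality function: positive and negative weights get
#' separate null models, the positive term is normalized by the total
#' positive strength and the negative term by the combined strength, so
#' within-module anti-correlations are penalized but cannot dominate:
#' \deqn{Q = \frac{1}{v^+}\sum_{ij}\left(w^+_{ij}-\gamma\frac{s^+_i s^+_j}{v^+}\right)\delta_{c_i c_j}
#'      - \frac{1}{v^+ + v^-}\sum_{ij}\left(w^-_{ij}-\gamma\frac{s^-_i s^-_j}{v^-}\right)\delta_{c_i c_j}}
#' Optimization is Louvain-style: greedy single-node moves to the best
#' community followed by greedy community merges, repeated to convergence;
#' the best partition over `n_runs` random-order restarts is kept.
#' Deterministic given `seed`.
#'
#' @param m Symmetric N x N matrix with zero diagonal (Fisher-z FC). With
#'   `negative_weights = "zero"` negative entries are removed first and the
#'   quality reduces to standard weighted Newman modularity.
#' @param gamma Resolution parameter (default 1).
#' @param n_runs Random restarts (default 100).
#' @param seed Integer seed.
#' @param negative_weights `"signed"` (default) or `"zero"`.
#' @return List of class `dfc_modularity`: `q`, `partition` (integer module
#'   labels, contiguous from 1), `n_modules`, `gamma`, `n_runs`, `seed`.
#' @examples
#' m <- rbind(
#'   cbind(matrix(1, 3, 3), matrix(-1, 3, 3)),
#'   cbind(matrix(-1, 3, 3), matrix(1, 3, 3))
#' )
#' diag(m) <- 0
#' louvain_modularity(m, n_runs = 10, seed = 1)$q
#' @export
louvain_modularity <- function(m, gamma = 1, n_runs = 100L, seed = 20230502L,
                               negative_weights = c("signed", "zero")) {
  negative_weights <- match.arg(negative_weights)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > 1e-10) abort("Matrix must be symmetric.")
  if (max(abs(diag(m))) > 1e-12) abort("Diagonal must be zero.")
  n <- nrow(m)
  if (negative_weights == "zero") m <- pmax(m, 0)
  if (all(m == 0)) {
    return(structure(
      list(
        q = 0, partition = rep(1L, n), n_modules = 1L, gamma = gamma,
        n_runs = n_runs, seed = seed
      ),
      class = "dfc_modularity"
    ))
  }
  beff <- signed_modularity_matrix(m, gamma)
  best <- withr::with_seed(seed, {
    best_q <- -Inf
    best_part <- seq_len(n)
    for (r in seq_len(n_runs)) {
      part <- louvain_once(beff)
      q <- sum(beff[outer(part, part, "==")])
      if (q > best_q + 1e-15) {
        best_q <- q
        best_part <- part
      }
    }
    list(q = best_q, partition = best_part)
  })
  part <- as.integer(factor(best$partition, levels = unique(best$partition)))
  structure(
    list(
      q = best$q, partition = part, n_modules = max(part), gamma = gamma,
      n_runs = as.integer(n_runs), seed = as.integer(seed)
    ),
    class = "dfc_modularity"
  )
}

#' @export
print.dfc_modularity <- function(x, ...) {
  cat(
    "<dfc_modularity> Q = ", format(x$q, digits = 5), ", ",
    x$n_modules, " modules (gamma = ", x$gamma, ")\n",
    sep = ""
  )
  invisible(x)
}

# Effective modularity matrix for the asymmetric signed quality function:
# Q(partition) = sum of beff over same-community pairs (including i = j).
signed_modularity_matrix <- function(m, gamma) {
  wp <- pmax(m, 0)
  wn <- pmax(-m, 0)
  vp <- sum(wp)
  vn <- sum(wn)
  bp <- if (vp > 0) (wp - gamma * outer(rowSums(wp), rowSums(wp)) / vp) / vp else 0 * m
  bn <- if (vn > 0) (wn - gamma * outer(rowSums(wn), rowSums(wn)) / vn) / (vp + vn) else 0 * m
  bp - bn
}

#' Signed modularity of a given partition
#'
#' Evaluates the asymmetric signed quality function (see
#' [louvain_modularity()]) for a fixed community assignment.
#'
#' @inheritParams louvain_modularity
#' @param partition Integer community labels, one per node.
#' @return Scalar Q.
#' @export
modularity_signed <- function(m, partition, gamma = 1) {
  stopifnot(length(partition) == nrow(m))
  beff <- signed_modularity_matrix(m, gamma)
  sum(beff[outer(partition, partition, "==")])
}

# One Louvain-style optimization pass on the effective modularity matrix:
# node moves in random order, then community merges, until no gain.
louvain_once <- function(beff) {
  n <- nrow(beff)
  part <- seq_len(n)
  eps <- 1e-12
  repeat {
    improved <- FALSE
    # phase 1: single-node moves
    repeat {
      moved <- FALSE
      for (i in sample.int(n)) {
        comms <- unique(part)
        # gain of i in community c (excluding i itself): 2 * sum(beff[i, members])
        link <- vapply(
          comms,
          function(c) sum(beff[i, part == c & seq_len(n) != i]),
          numeric(1)
        )
        cur <- link[comms == part[i]]
        best <- which.max(link)
        if (link[best] > cur + eps) {
          part[i] <- comms[best]
          moved <- TRUE
          improved <- TRUE
        }
      }
      if (!moved) break
    }
    # phase 2: greedy community merges
    repeat {
      comms <- unique(part)
      nc <- length(comms)
      if (nc < 2) break
      gain_best <- eps
      pair_best <- NULL
      for (a in seq_len(nc - 1)) {
        ia <- part == comms[a]
        for (b in (a + 1):nc) {
          g <- 2 * sum(beff[ia, part == comms[b]])
          if (g > gain_best) {
            gain_best <- g
            pair_best <- c(a, b)
          }
        }
      }
      if (is.null(pair_best)) break
      part[part == comms[pair_best[2]]] <- comms[pair_best[1]]
      improved <- TRUE
    }
    if (!improved) break
  }
  part
}

#' Within-network functional connectivity
#'
#' Mean of the off-diagonal entries among a network's ROIs (each unordered
#' pair counted once).
#'
#' @param m Symmetric FC matrix in canonical ROI order.
#' @param network Network label.
#' @param parcellation A [parcellation()].
#' @return Scalar mean within-network connectivity.
#' @export
within_network_fc <- function(m, network, parcellation) {
  idx <- which(as.character(parcellation$network) == network)
  if (length(idx) < 2) abort(paste0("Unknown or too-small network: ", network))
  sub <- m[idx, idx]
  mean(sub[lower.tri(sub)])
}

#' Between-network functional connectivity
#'
#' Mean connectivity between a network's ROIs and every ROI outside it.
#'
#' @inheritParams within_network_fc
#' @return Scalar mean between-network connectivity.
#' @export
between_network_fc <- function(m, network, parcellation) {
  idx <- which(as.character(parcellation$network) == network)
  if (!length(idx)) abort(paste0("Unknown network: ", network))
  mean(m[idx, -idx])
}

#' Per-network within/between connectivity table
#'
#' @inheritParams within_network_fc
#' @return Tibble `network`, `wnfc`, `bnfc`, `segregation`
#'   (`(wnfc - bnfc) / wnfc`, `NA` when `wnfc <= 0`).
#' @export
network_fc_table <- function(m, parcellation) {
  nets <- levels(parcellation$network)
  rows <- purrr::map(nets, function(nw) {
    w <- within_network_fc(m, nw, parcellation)
    b <- between_network_fc(m, nw, parcellation)
    tibble(
      network = nw, wnfc = w, bnfc = b,
      segregation = if (w > 0) (w - b) / w else NA_real_
    )
  })
  bind_rows(rows)
}

#' System segregation of an FC matrix
#'
#' For each network, `(WNFC - BNFC) / WNFC`; the system segregation score is
#' the mean over networks. Networks with non-positive WNFC have undefined
#' segregation and are excluded from the mean with a warning; the count of
#' exclusions is attached as attribute `n_excluded`.
#'
#' @inheritParams within_network_fc
#' @return Scalar segregation with attribute `n_excluded`.
#' @examples
#' p <- default_parcellation()
#' s <- default_state_covariances(p)
#' system_segregation(fisher_z(s[[1]] - diag(30)), p) # segregated state
#' @export
system_segregation <- function(m, parcellation) {
  tab <- network_fc_table(m, parcellation)
  n_excl <- sum(is.na(tab$segregation))
  if (n_excl > 0) {
    warn(sprintf(
      "%d network(s) with non-positive WNFC excluded from system segregation.",
      n_excl
    ))
  }
  out <- mean(tab$segregation, na.rm = TRUE)
  attr(out, "n_excluded") <- n_excl
  out
}

#' Graph metrics for a table of FC matrices
#'
#' Applies [louvain_modularity()] and [system_segregation()] to every matrix
#' in a `fc` list column (as produced by [subject_state_matrices()] or
#' [static_fc()]).
#'
#' @param fc_table Tibble with a list column `fc` of symmetric zero-diagonal
#'   matrices.
#' @param parcellation A [parcellation()].
#' @param gamma,n_runs,seed,negative_weights Passed to
#'   [louvain_modularity()].
#' @return The input tibble with added columns `modularity`, `n_modules`,
#'   `segregation`, `n_networks_excluded`.
#' @export
graph_metrics <- function(fc_table, parcellation, gamma = 1, n_runs = 100L,
                          seed = 20230502L,
                          negative_weights = c("signed", "zero")) {
  negative_weights <- match.arg(negative_weights)
  res <- purrr::imap(fc_table$fc, function(m, i) {
    lv <- louvain_modularity(
      m, gamma, n_runs, subject_seed(seed, i),
      negative_weights
    )
    seg <- suppressWarnings(system_segregation(m, parcellation))
    tibble(
      modularity = lv$q, n_modules = lv$n_modules,
      segregation = as.numeric(seg),
      n_networks_excluded = attr(seg, "n_excluded")
    )
  })
  dplyr::bind_cols(fc_table, bind_rows(res))
}
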