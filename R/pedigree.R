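#' Honeybee pedigrees with queens, worker groups and pseudo-sires
#'
#' A bee pedigree stores one node per queen (breeding queens and
#' drone-producing queens alike), one per phenotyped colony's worker group,
#' and one per open-mating pseudo-sire (a pool of unknown, unrelated dummy
#' DPQs supplying base drones). Every node's additive value is represented
#' as a weighted sum of its parent nodes' values plus an independent
#' Mendelian-sampling residual; the weights and residual variances encode
#' haplodiploid inheritance:
#'
#' * a queen takes 0.5 from her dam and, when her father drone comes from a
#'   single DPQ, 0.5 from that DPQ; a drone is a single gamete of its
#'   mother, so the DPQ enters exactly like a diploid sire. Open-mated
#'   matings take coefficient 1 on the pseudo-sire row (the pool average).
#' * a worker group takes 0.5 from its queen and the sire-side coefficient
#'   of the mating; its residual variance is the paternal sampling variance
#'   of the finite set of `n_drones` drones, maternal deviations averaging
#'   out over the (infinitely many) workers.
#'
#' This representation gives the dense relationship matrix by forward
#' recursion ([compute_A()]), a sparse inverse directly from the
#' coefficients ([compute_A_inverse()]), and inbreeding coefficients
#' \eqn{F} as half the relationship between a queen's dam and her genetic
#' sire.
#'
#' @param n_drones polyandry level used for matings (default 8).
#' @param n_dummy_dpq dummy DPQs per open-mating pseudo-sire (default 100).
#' @return An object of class `bee_pedigree` (environment-backed; grows in
#'   amortized constant time).
#' @seealso [add_node()], [compute_A()], [compute_A_inverse()],
#'   [gene_drop_A()]
#' @export
bee_pedigree <- function(n_drones = 8L, n_dummy_dpq = 100L) {
  ped <- new.env(parent = emptyenv())
  ped$n <- 0L
  cap <- 256L
  ped$kind <- integer(cap)       # 1 queen, 2 worker group, 3 pseudo-sire
  ped$dam <- integer(cap)
  ped$sire <- integer(cap)
  ped$year <- integer(cap)
  ped$label <- character(cap)
  ped$c1 <- numeric(cap)         # coefficient on dam
  ped$c2 <- numeric(cap)         # coefficient on sire
  ped$d <- numeric(cap)          # Mendelian-sampling (residual) variance
  ped$F <- numeric(cap)          # inbreeding (queens; NA otherwise)
  ped$n_drones <- as.integer(n_drones)
  ped$n_dummy_dpq <- as.integer(n_dummy_dpq)
  class(ped) <- "bee_pedigree"
  ped
}

KIND_QUEEN <- 1L
KIND_WORKER_GROUP <- 2L
KIND_PSEUDO_SIRE <- 3L
kind_labels <- c("QUEEN", "WORKER_GROUP", "PSEUDO_SIRE")

# variance of the pool-average row of a pseudo-sire (A scale)
pseudo_sire_var <- function(n_dummy_dpq) 0.25 / n_dummy_dpq

# variance of the mean gametic value of n_drones drones drawn from a pool
# of n_dummy_dpq unrelated non-inbred dams
open_mating_mean_var <- function(n_drones, n_dummy_dpq) {
  0.5 / n_drones + (1 - 1 / n_drones) * 0.25 / n_dummy_dpq
}

ped_grow <- function(ped, need) {
  cap <- length(ped$kind)
  if (need <= cap) return(invisible(ped))
  new_cap <- max(need, 2L * cap)
  for (fld in c("kind", "dam", "sire", "year")) {
    v <- ped[[fld]]; length(v) <- new_cap; v[is.na(v)] <- 0L; ped[[fld]] <- v
  }
  v <- ped$label; length(v) <- new_cap; v[is.na(v)] <- ""; ped$label <- v
  for (fld in c("c1", "c2", "d", "F")) {
    v <- ped[[fld]]; length(v) <- new_cap; ped[[fld]] <- v
  }
  invisible(ped)
}

#' Append a node to a bee pedigree
#'
#' Parents must already be present (topological order is maintained by
#' construction). Founder queens and pseudo-sires take no parents. A
#' queen's `sire` is the node that supplied her father drone: a QUEEN node
#' (the single DPQ whose drones inseminated her dam) or a PSEUDO_SIRE node
#' (open mating). A worker group's `dam` is its queen and its `sire` the
#' queen's own mate.
#'
#' @param ped a [bee_pedigree()].
#' @param kind one of `"QUEEN"`, `"WORKER_GROUP"`, `"PSEUDO_SIRE"`.
#' @param dam,sire parent node ids (integers), or `NA` for base nodes.
#' @param birth_year optional integer year.
#' @param label optional external identifier (kept in CSV round trips).
#' @param n_drones polyandry of the mating behind this node; defaults to
#'   the pedigree-wide setting.
#' @return the new node id (integer).
#' @export
add_node <- function(ped, kind, dam = NA, sire = NA, birth_year = NA,
                     label = NULL, n_drones = NULL) {
  stopifnot(inherits(ped, "bee_pedigree"))
  kind <- match(match.arg(kind, kind_labels), kind_labels)
  dam <- if (is.na(dam)) 0L else as.integer(dam)
  sire <- if (is.na(sire)) 0L else as.integer(sire)
  n <- ped$n
  if (dam > n || sire > n || dam < 0L || sire < 0L) {
    stop("unknown parent id: parents must precede children")
  }
  if (dam > 0L && ped$kind[dam] != KIND_QUEEN) {
    stop("dam must be a QUEEN node")
  }
  if (sire > 0L && !(ped$kind[sire] %in% c(KIND_QUEEN, KIND_PSEUDO_SIRE))) {
    stop("sire must be a QUEEN (DPQ) or PSEUDO_SIRE node")
  }
  nd <- if (is.null(n_drones)) ped$n_drones else as.integer(n_drones)
  id <- n + 1L
  ped_grow(ped, id)
  v_pool <- pseudo_sire_var(ped$n_dummy_dpq)
  if (kind == KIND_PSEUDO_SIRE) {
    if (dam > 0L || sire > 0L) stop("pseudo-sires are base nodes")
    c1 <- c2 <- 0; dd <- v_pool; F_ <- NA_real_
  } else if (kind == KIND_QUEEN) {
    if (xor(dam > 0L, sire > 0L)) {
      stop("queens need either both parents or none (founder)")
    }
    if (dam == 0L) {                 # founder
      c1 <- c2 <- 0; dd <- 1; F_ <- 0
    } else if (ped$kind[sire] == KIND_QUEEN) {
      c1 <- 0.5; c2 <- 0.5
      dd <- 0.25 * (1 - ped$F[dam]) + 0.25 * (1 - ped$F[sire])
      F_ <- 0.5 * ped_rel(ped, dam, sire)
    } else {                         # open mating
      c1 <- 0.5; c2 <- 1
      dd <- 0.25 * (1 - ped$F[dam]) + (0.5 - v_pool)
      F_ <- ped_rel(ped, dam, sire)
    }
  } else {                           # worker group
    if (dam == 0L || sire == 0L) stop("worker groups need a queen and a mate")
    if (ped$kind[dam] != KIND_QUEEN) stop("a worker group's dam is its queen")
    if (ped$kind[sire] == KIND_QUEEN) {
      c1 <- 0.5; c2 <- 0.5
      dd <- 0.25 * (1 - ped$F[sire]) / nd
    } else {
      c1 <- 0.5; c2 <- 1
      dd <- open_mating_mean_var(nd, ped$n_dummy_dpq) - v_pool
    }
    F_ <- NA_real_
  }
  ped$n <- id
  ped$kind[id] <- kind; ped$dam[id] <- dam; ped$sire[id] <- sire
  ped$year[id] <- if (is.na(birth_year)) NA_integer_ else as.integer(birth_year)
  ped$label[id] <- if (is.null(label)) sprintf("N%d", id) else as.character(label)
  ped$c1[id] <- c1; ped$c2[id] <- c2; ped$d[id] <- dd; ped$F[id] <- F_
  id
}

# Fast internal batch append for the scheme engine: all vectors same length.
# F for queens must be supplied (computed from the unique dam/mate pairs);
# worker groups / pseudo-sires get NA.
ped_add_batch <- function(ped, kind, dam, sire, year, F, c1, c2, d, label = NULL) {
  m <- length(kind)
  ids <- ped$n + seq_len(m)
  ped_grow(ped, ped$n + m)
  ped$kind[ids] <- kind; ped$dam[ids] <- dam; ped$sire[ids] <- sire
  ped$year[ids] <- year; ped$F[ids] <- F
  ped$c1[ids] <- c1; ped$c2[ids] <- c2; ped$d[ids] <- d
  ped$label[ids] <- if (is.null(label)) sprintf("N%d", ids) else label
  ped$n <- ped$n + m
  ids
}

#' Pairwise expected additive relationship
#'
#' Computes single entries of the relationship matrix without forming it,
#' by traversing the genome-source decomposition `A = T D T'` of the
#' pedigree recursion. Used internally to obtain inbreeding coefficients
#' of new queens.
#'
#' @param ped a [bee_pedigree()].
#' @param x,y node ids (vectors of equal length are paired elementwise).
#' @return numeric vector of relationships.
#' @export
ped_rel <- function(ped, x, y) {
  n <- ped$n
  rel_pairs_cpp(ped$dam[seq_len(n)], ped$sire[seq_len(n)],
                ped$c1[seq_len(n)], ped$c2[seq_len(n)], ped$d[seq_len(n)],
                as.integer(x), as.integer(y))
}

#' @export
print.bee_pedigree <- function(x, ...) {
  n <- x$n
  k <- tabulate(x$kind[seq_len(n)], 3L)
  cat(sprintf(
    "bee_pedigree: %d nodes (%d queens, %d worker groups, %d pseudo-sires)\n",
    n, k[1], k[2], k[3]))
  qs <- which(x$kind[seq_len(n)] == KIND_QUEEN)
  if (length(qs)) {
    cat(sprintf("  mean queen inbreeding F = %.4f\n", mean(x$F[qs])))
  }
  invisible(x)
}

#' Dense relationship matrix of a bee pedigree
#'
#' Forward tabular recursion over nodes. Intended for pedigrees up to a few
#' thousand nodes (validation, small evaluations); the simulation engine
#' only ever forms the sparse inverse.
#'
#' @param ped a [bee_pedigree()].
#' @return list with the dense symmetric matrix `A` and the vector `F` of
#'   queen inbreeding coefficients (`NA` for non-queen nodes).
#' @export
compute_A <- function(ped) {
  n <- ped$n
  if (n > 5000L) stop("dense A is only materialized for pedigrees <= 5000 nodes")
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    p <- c(ped$dam[i], ped$sire[i]); cc <- c(ped$c1[i], ped$c2[i])
    keep <- p > 0L
    p <- p[keep]; cc <- cc[keep]
    if (length(p)) {
      if (i > 1L) {
        prev <- seq_len(i - 1L)
        arow <- drop(A[prev, p, drop = FALSE] %*% cc)
        A[prev, i] <- arow
        A[i, prev] <- arow
      }
      App <- A[p, p, drop = FALSE]
      A[i, i] <- drop(crossprod(cc, App %*% cc)) + ped$d[i]
    } else {
      A[i, i] <- ped$d[i]
    }
  }
  dimnames(A) <- list(ped$label[seq_len(n)], ped$label[seq_len(n)])
  list(A = A, F = ped$F[seq_len(n)])
}

#' Sparse inverse relationship matrix
#'
#' Built directly from the pedigree recursion in one pass (generalized
#' Henderson rules): each node contributes
#' \eqn{(e_i - c_i)(e_i - c_i)'/d_i} where \eqn{c_i} holds its parent
#' coefficients and \eqn{d_i} its Mendelian-sampling variance. On small
#' pedigrees this equals the dense inverse of [compute_A()] to numerical
#' precision.
#'
#' @param ped a [bee_pedigree()].
#' @return a `dsCMatrix` (symmetric sparse) inverse relationship matrix.
#' @export
compute_A_inverse <- function(ped) {
  n <- ped$n
  idx <- seq_len(n)
  d <- ped$d[idx]
  if (any(d <= 1e-12)) {
    stop("singular relationship matrix: a node has (near-)zero ",
         "Mendelian-sampling variance")
  }
  dam <- ped$dam[idx]; sire <- ped$sire[idx]
  c1 <- ped$c1[idx]; c2 <- ped$c2[idx]
  w <- 1 / d
  has1 <- dam > 0L; has2 <- sire > 0L; has12 <- has1 & has2
  ii <- c(idx,
          idx[has1], dam[has1],
          idx[has2], sire[has2],
          dam[has12], sire[has12],
          dam[has1], sire[has2])
  jj <- c(idx,
          dam[has1], idx[has1],
          sire[has2], idx[has2],
          sire[has12], dam[has12],
          dam[has1], sire[has2])
  xx <- c(w,
          -c1[has1] * w[has1], -c1[has1] * w[has1],
          -c2[has2] * w[has2], -c2[has2] * w[has2],
          (c1 * c2 * w)[has12], (c1 * c2 * w)[has12],
          (c1^2 * w)[has1], (c2^2 * w)[has2])
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Matrix::forceSymmetric(M)
}

#' Per-year mean inbreeding of a cohort of queens
#'
#' Summarizes inbreeding coefficients of queens by birth year and reports
#' the change relative to a reference cohort, in percent.
#'
#' @param ped a [bee_pedigree()].
#' @param ids queen node ids to include (e.g. candidate dams); defaults to
#'   all queens with a birth year.
#' @param reference_year cohort against which added inbreeding is expressed
#'   (default: the earliest year present).
#' @return data.frame with columns `year`, `n`, `mean_F`, and
#'   `added_F_pct` (percentage points relative to the reference cohort).
#' @export
inbreeding_trajectory <- function(ped, ids = NULL, reference_year = NULL) {
  n <- ped$n
  if (is.null(ids)) {
    ids <- which(ped$kind[seq_len(n)] == KIND_QUEEN & !is.na(ped$year[seq_len(n)]))
  }
  if (!length(ids)) stop("no queens selected")
  yr <- ped$year[ids]; F_ <- ped$F[ids]
  agg <- stats::aggregate(F_, by = list(year = yr), FUN = mean)
  cnt <- as.integer(table(factor(yr, levels = agg$year)))
  if (is.null(reference_year)) reference_year <- min(agg$year)
  ref <- agg$x[match(reference_year, agg$year)]
  if (is.na(ref)) stop("reference year has no queens")
  data.frame(year = agg$year, n = cnt, mean_F = agg$x,
             added_F_pct = 100 * (agg$x - ref))
}

#' Write / read a bee pedigree as CSV
#'
#' One row per node with columns `id`, `kind`, `dam_id`, `sire_id`,
#' `n_drones`, `birth_year`. Ids are the node labels (opaque strings);
#' parents must precede children.
#'
#' @param ped a [bee_pedigree()].
#' @param file path.
#' @return `write_pedigree_csv` returns the file invisibly;
#'   `read_pedigree_csv` returns a rebuilt [bee_pedigree()].
#' @export
write_pedigree_csv <- function(ped, file) {
  n <- ped$n
  lab <- ped$label[seq_len(n)]
  df <- data.frame(
    id = lab,
    kind = kind_labels[ped$kind[seq_len(n)]],
    dam_id = ifelse(ped$dam[seq_len(n)] > 0L, lab[pmax(ped$dam[seq_len(n)], 1L)], ""),
    sire_id = ifelse(ped$sire[seq_len(n)] > 0L, lab[pmax(ped$sire[seq_len(n)], 1L)], ""),
    n_drones = ped$n_drones,
    birth_year = ped$year[seq_len(n)]
  )
  data.table::fwrite(df, file)
  invisible(file)
}

#' @rdname write_pedigree_csv
#' @param n_drones,n_dummy_dpq pedigree-wide settings used when rebuilding.
#' @export
read_pedigree_csv <- function(file, n_drones = 8L, n_dummy_dpq = 100L) {
  df <- data.table::fread(file, colClasses = list(character = c("id", "dam_id", "sire_id")))
  ped <- bee_pedigree(n_drones = n_drones, n_dummy_dpq = n_dummy_dpq)
  lookup <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(df))) {
    dam <- if (nzchar(df$dam_id[r])) get0(df$dam_id[r], envir = lookup) else NA
    sire <- if (nzchar(df$sire_id[r])) get0(df$sire_id[r], envir = lookup) else NA
    if (is.null(dam) || is.null(sire)) {
      stop("row ", r, ": parent id not seen yet (parents must precede children)")
    }
    id <- add_node(ped, df$kind[r], dam = dam, sire = sire,
                   birth_year = df$birth_year[r], label = df$id[r])
    assign(df$id[r], id, envir = lookup)
  }
  ped
}
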