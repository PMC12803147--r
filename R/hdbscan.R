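#' Density-based clustering with noise (HDBSCAN)
#'
#' Hierarchical DBSCAN on Euclidean distances: core distances at
#' `min_samples` neighbours, mutual-reachability transform, single-linkage
#' hierarchy, condensed tree at `min_cluster_size`, and excess-of-mass
#' (stability) cluster selection. Points in no selected cluster are
#' labelled 0 (noise). Used by [reject_outlier_waveforms()] to drop
#' waveforms that fall outside dense clusters; exposed because it is
#' independently useful and independently tested.
#'
#' @param X Numeric matrix, one observation per row.
#' @param min_cluster_size Smallest cluster size considered real.
#' @param min_samples Neighbour count for core distances (defaults to
#'   `min_cluster_size`).
#' @param allow_single_cluster Permit the hierarchy root itself to be
#'   selected (sensible when the data may form one homogeneous cluster).
#' @return Integer labels, one per row; 0 marks noise.
#' @export
hdbscan_labels <- function(X, min_cluster_size = 20,
                           min_samples = min_cluster_size,
                           allow_single_cluster = TRUE) {
  n <- nrow(X)
  mcs <- max(2L, as.integer(min_cluster_size))
  if (n < mcs) return(rep(0L, n))
  dmat <- as.matrix(stats::dist(X))
  k <- min(min_samples, n)
  core <- apply(dmat, 1L, function(r) sort(r, partial = k)[k])
  mreach <- pmax(dmat, outer(core, core, pmax))
  diag(mreach) <- 0
  hc <- stats::hclust(stats::as.dist(mreach), method = "single")

  m <- n - 1L
  merge <- hc$merge
  lambda_at <- 1 / pmax(hc$height, 1e-12)

  node_size <- integer(m)
  for (i in seq_len(m)) {
    node_size[i] <- sum(ifelse(merge[i, ] < 0, 1L, node_size[pmax(merge[i, ], 1L)]))
  }
  collect_points <- function(node) {
    if (node < 0) return(-node)
    out <- integer(0); stack <- node
    while (length(stack)) {
      nd <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (ch in merge[nd, ]) {
        if (ch < 0) out <- c(out, -ch) else stack <- c(stack, ch)
      }
    }
    out
  }
  size_of <- function(node) if (node < 0) 1L else node_size[node]

  # condensed-tree bookkeeping
  cid_parent <- integer(0); cid_birth <- numeric(0)
  cid_size <- integer(0); cid_leave_sum <- numeric(0)
  leave_cid <- integer(n)                       # cluster each point fell out of
  new_cid <- function(parent, birth, size) {
    cid_parent[[length(cid_parent) + 1L]] <<- parent
    cid_birth[[length(cid_birth) + 1L]] <<- birth
    cid_size[[length(cid_size) + 1L]] <<- size
    cid_leave_sum[[length(cid_leave_sum) + 1L]] <<- 0
    length(cid_parent)
  }
  root_cid <- new_cid(0L, 0, n)
  walk <- function(node, cid) {
    cur <- node
    remaining <- size_of(node)
    repeat {
      lam <- lambda_at[cur]
      ch <- merge[cur, ]
      s <- c(size_of(ch[1]), size_of(ch[2]))
      big <- s >= mcs
      if (all(big)) {
        cid_leave_sum[cid] <<- cid_leave_sum[cid] + remaining * lam
        for (b in 1:2) {
          child_cid <- new_cid(cid, lam, s[b])
          walk(ch[b], child_cid)
        }
        break
      } else if (any(big)) {
        drop_side <- which(!big)
        for (b in drop_side) {
          pts <- collect_points(ch[b])
          leave_cid[pts] <<- cid
          cid_leave_sum[cid] <<- cid_leave_sum[cid] + length(pts) * lam
          remaining <- remaining - length(pts)
        }
        cur <- ch[big][1]
        if (cur < 0) {                          # mcs == 1 guard; cannot happen
          leave_cid[-cur] <<- cid
          cid_leave_sum[cid] <<- cid_leave_sum[cid] + lam
          break
        }
      } else {
        pts <- collect_points(cur)
        leave_cid[pts] <<- cid
        cid_leave_sum[cid] <<- cid_leave_sum[cid] + length(pts) * lam
        break
      }
    }
  }
  walk(m, root_cid)

  n_cid <- length(cid_parent)
  stability <- cid_leave_sum - cid_size * cid_birth
  children <- split(seq_len(n_cid)[-1], cid_parent[-1])
  selected <- logical(n_cid)
  subtree_stab <- numeric(n_cid)
  subtree_sel <- vector("list", n_cid)
  for (cid in rev(seq_len(n_cid))) {            # children created after parents
    kids <- children[[as.character(cid)]]
    if (is.null(kids)) {
      selected[cid] <- TRUE
      subtree_stab[cid] <- stability[cid]
      subtree_sel[[cid]] <- cid
    } else {
      kid_sum <- sum(subtree_stab[kids])
      can_select <- cid != root_cid || allow_single_cluster
      if (can_select && stability[cid] > kid_sum) {
        selected[cid] <- TRUE
        subtree_stab[cid] <- stability[cid]
        subtree_sel[[cid]] <- cid
      } else {
        subtree_stab[cid] <- max(kid_sum, if (can_select) stability[cid] else -Inf)
        subtree_sel[[cid]] <- unlist(subtree_sel[kids])
      }
    }
  }
  chosen <- subtree_sel[[root_cid]]
  selected <- seq_len(n_cid) %in% chosen

  # label = lowest selected ancestor of the cluster each point fell out of
  labels <- integer(n)
  label_map <- integer(n_cid)
  relabel <- 0L
  lowest_selected <- function(cid) {
    while (cid != 0L && !selected[cid]) cid <- cid_parent[cid]
    cid
  }
  for (p in seq_len(n)) {
    anc <- lowest_selected(leave_cid[p])
    if (anc == 0L) next
    if (label_map[anc] == 0L) {
      relabel <- relabel + 1L
      label_map[anc] <- relabel
    }
    labels[p] <- label_map[anc]
  }
  labels
}
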