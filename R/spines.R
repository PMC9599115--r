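#' Place explicit dendritic spines on a morphology
#'
#' Spines are placed uniformly at random over the eligible dendritic arc
#' length, i.e. the portions of dendritic segments whose path distance from
#' the soma exceeds `min_distance_um`. The spine count is the eligible
#' length times the density, deterministically rounded. Every spine has a
#' cylindrical head (0.5 µm diameter and length) and neck (0.12 µm diameter,
#' 0.5 µm length).
#'
#' @param morph a `morphology`
#' @param density_per_um spine density on eligible dendrite (1/µm); 0.1 for
#'   distributed-input experiments, 0.75-2.75 on selected segments for
#'   clustered-input experiments
#' @param min_distance_um minimum path distance from the soma (µm)
#' @param seed integer seed
#' @param segments optional segment ids to restrict placement to (subset
#'   used for high-density clustered placement)
#' @return a `spine_set`: data.frame with `spine_id`, `segment_id`,
#'   `arc_pos_um` (from the proximal segment end), `path_distance_um`;
#'   spine geometry in `attr(, "geometry")`
#' @export
place_spines <- function(morph, density_per_um = 0.1, min_distance_um = 25,
                         seed = 1, segments = NULL) {
  stopifnot(inherits(morph, "morphology"), density_per_um >= 0)
  dend <- morph[-1, , drop = FALSE]
  if (!is.null(segments)) dend <- dend[dend$segment_id %in% segments, ]
  # eligible arc interval within each segment
  lo <- pmax(0, min_distance_um - dend$path_start_um)
  elig <- pmax(0, dend$length_um - lo)
  total <- sum(elig)
  n <- round(density_per_um * total)
  geom <- list(head_diam_um = 0.5, head_len_um = 0.5, neck_diam_um = 0.12,
               neck_len_um = 0.5)
  if (n == 0) {
    out <- data.frame(spine_id = integer(0), segment_id = integer(0),
                      arc_pos_um = numeric(0), path_distance_um = numeric(0))
    attr(out, "geometry") <- geom
    class(out) <- c("spine_set", "data.frame")
    return(out)
  }
  set.seed(as.integer(seed))
  u <- sort(stats::runif(n, 0, total))
  edges <- cumsum(elig)
  seg_i <- findInterval(u, c(0, edges[-length(edges)] + 1e-12)) # bin index
  seg_i <- pmin(pmax(seg_i, 1L), length(elig))
  within <- u - c(0, edges)[seg_i]
  arc <- lo[seg_i] + within
  # deterministic jitter so no two spines coincide
  pd <- dend$path_start_um[seg_i] + arc
  ord <- order(seg_i, arc)
  for (i in which(duplicated(round(pd, 6))))
    arc[i] <- min(arc[i] + 0.01, dend$length_um[seg_i[i]])
  out <- data.frame(spine_id = seq_len(n), segment_id = dend$segment_id[seg_i],
                    arc_pos_um = arc,
                    path_distance_um = dend$path_start_um[seg_i] + arc)
  if (any(out$path_distance_um <= min_distance_um))
    out <- out[out$path_distance_um > min_distance_um, , drop = FALSE]
  out$spine_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "geometry") <- geom
  class(out) <- c("spine_set", "data.frame")
  out
}

#' Pairwise dendritic path distances between spines
#'
#' @param morph a `morphology`
#' @param spines a `spine_set`
#' @return symmetric matrix of path distances (µm)
#' @export
spine_distance_matrix <- function(morph, spines) {
  n <- nrow(spines)
  d <- matrix(0, n, n)
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    d[i, j] <- d[j, i] <- path_distance(
      morph, spines$segment_id[i], spines$arc_pos_um[i],
      spines$segment_id[j], spines$arc_pos_um[j])
  }
  d
}

#' Nearest-neighbor ordering of spines
#'
#' Neighbor order is by dendritic path distance between spine attachment
#' points, ties broken by `spine_id`, giving a deterministic "k nearest
#' neighbors" for the analysis module.
#'
#' @param dmat distance matrix from [spine_distance_matrix()]
#' @param k number of neighbors
#' @return integer matrix (n spines x k) of neighbor spine row indices
#' @export
nearest_neighbors <- function(dmat, k) {
  n <- nrow(dmat)
  k <- min(k, n - 1)
  t(vapply(seq_len(n), function(i) {
    ord <- order(dmat[i, ], seq_len(n))
    ord <- ord[ord != i]
    ord[seq_len(k)]
  }, integer(k)))
}

#' Cluster configuration
#'
#' @param spines_per_cluster spines in one cluster, `>= 1`
#' @param cluster_length maximum dendritic distance between the most
#'   separated pair of spines in a cluster (µm)
#' @param n_mappings number of independent mappings to draw
#' @param seed integer seed
#' @return an object of class `cluster_config`
#' @export
cluster_config <- function(spines_per_cluster, cluster_length, n_mappings = 1,
                           seed) {
  stopifnot(spines_per_cluster >= 1, cluster_length >= 0, n_mappings >= 1)
  if (missing(seed)) stop("seed is a mandatory field of cluster_config")
  structure(list(spines_per_cluster = as.integer(spines_per_cluster),
                 cluster_length = cluster_length,
                 n_mappings = as.integer(n_mappings),
                 seed = as.integer(seed)),
            class = "cluster_config")
}

#' Assign spike trains to clustered spines
#'
#' Greedy construction: cluster anchor spines are drawn uniformly over the
#' remaining eligible spines; members are added in order of increasing path
#' distance to the anchor, subject to the constraint that the maximum
#' pairwise dendritic distance within the cluster stays `<= cluster_length`.
#' Each of the `n_trains` trains is assigned to exactly one spine
#' (injective); unassigned spines receive no train.
#'
#' @param morph a `morphology`
#' @param spines a `spine_set`
#' @param n_trains number of trains to assign
#' @param cfg a [cluster_config()]
#' @param dmat optional precomputed [spine_distance_matrix()]
#' @return a `cluster_mapping`: data.frame with `train_id`, `spine_id`,
#'   `cluster_id`; realized cluster spans in `attr(, "cluster_span_um")`
#' @export
assign_clusters <- function(morph, spines, n_trains, cfg, dmat = NULL) {
  stopifnot(inherits(cfg, "cluster_config"))
  m <- cfg$spines_per_cluster
  if (n_trains > nrow(spines))
    stop("not enough eligible spines (", nrow(spines), ") for ", n_trains,
         " trains")
  if (is.null(dmat)) dmat <- spine_distance_matrix(morph, spines)
  set.seed(cfg$seed)
  avail <- rep(TRUE, nrow(spines))
  assigned <- integer(0); cluster_of <- integer(0)
  spans <- numeric(0)
  cl <- 0L
  while (length(assigned) < n_trains) {
    need <- min(m, n_trains - length(assigned))
    cand_anchors <- sample(which(avail))
    ok <- FALSE
    for (a in cand_anchors) {
      members <- a
      if (need > 1) {
        # candidates ordered by distance to anchor, ties by spine id
        ord <- order(dmat[a, ], seq_len(nrow(spines)))
        for (j in ord) {
          if (!avail[j] || j == a) next
          if (max(dmat[j, members]) <= cfg$cluster_length + 1e-9) {
            members <- c(members, j)
            if (length(members) == need) break
          }
        }
      }
      if (length(members) == need) { ok <- TRUE; break }
    }
    if (!ok)
      stop("infeasible cluster configuration: cannot place ", need,
           " spines within cluster_length = ", cfg$cluster_length,
           " um at the available spine density")
    cl <- cl + 1L
    avail[members] <- FALSE
    assigned <- c(assigned, members)
    cluster_of <- c(cluster_of, rep(cl, length(members)))
    spans <- c(spans, if (length(members) > 1)
      max(dmat[members, members]) else 0)
  }
  out <- data.frame(train_id = seq_len(n_trains),
                    spine_id = spines$spine_id[assigned],
                    cluster_id = cluster_of)
  attr(out, "cluster_span_um") <- spans
  attr(out, "config") <- cfg
  class(out) <- c("cluster_mapping", "data.frame")
  out
}

#' Draw several independent cluster mappings
#'
#' @inheritParams assign_clusters
#' @return list of `cluster_mapping` objects, drawn with seeds
#'   `cfg$seed + 0:(n_mappings-1)`
#' @export
assign_cluster_mappings <- function(morph, spines, n_trains, cfg,
                                    dmat = NULL) {
  if (is.null(dmat)) dmat <- spine_distance_matrix(morph, spines)
  lapply(seq_len(cfg$n_mappings) - 1L, function(k) {
    cfg_k <- cfg; cfg_k$seed <- cfg$seed + k
    assign_clusters(morph, spines, n_trains, cfg_k, dmat = dmat)
  })
}

#' Write a cluster mapping as CSV
#' @param mapping a `cluster_mapping`
#' @param path file path
#' @export
write_cluster_mapping <- function(mapping, path) {
  utils::write.csv(as.data.frame(mapping), path, row.names = FALSE)
  invisible(path)
}
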