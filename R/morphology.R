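#' Build a reduced dendritic morphology
#'
#' Constructs a simplified tree morphology standing in for a full
#' reconstruction: a spherical-equivalent soma with `n_primary` primary
#' dendrites, each consisting of `split_after` proximal segments and then
#' (optionally) splitting into `n_secondary` secondary branches, so that the
#' proximal/distal distinction and branch-local neighborhoods of a spiny
#' projection neuron are preserved at desk scale. Diameters taper linearly
#' from `diam_primary` at the soma to `diam_tip` at branch tips.
#'
#' @param n_primary number of primary dendrites
#' @param segments_per_branch segments along one soma-to-tip path
#' @param seg_length segment length (µm)
#' @param split_after primary segments before the branch point; use
#'   `n_secondary = 1` (or `split_after >= segments_per_branch`) for
#'   unbranched dendrites
#' @param n_secondary secondary branches per primary dendrite
#' @param soma_diameter soma diameter (µm)
#' @param diam_primary,diam_tip dendritic diameter at soma and at tips (µm)
#' @return a `morphology`: data.frame with columns `segment_id`, `parent_id`
#'   (0 = none, i.e. the soma), `length_um`, `diameter_um`, `path_start_um`
#'   (path distance from soma to the proximal end) and `path_mid_um`
#'   (to the midpoint); row 1 is the soma
#' @export
build_default_morphology <- function(n_primary = 4, segments_per_branch = 8,
                                     seg_length = 16, split_after = 2,
                                     n_secondary = 2, soma_diameter = 14,
                                     diam_primary = 2.2, diam_tip = 0.8) {
  stopifnot(n_primary >= 1, segments_per_branch >= 1, seg_length > 0,
            n_secondary >= 1, split_after >= 0)
  split_after <- min(split_after, segments_per_branch)
  rows <- list(data.frame(segment_id = 1L, parent_id = 0L,
                          length_um = soma_diameter,
                          diameter_um = soma_diameter, path_start_um = 0,
                          path_mid_um = 0))
  nid <- 1L
  total <- segments_per_branch
  diam_at <- function(k) # k = segment index along the path, 1-based
    diam_primary + (diam_tip - diam_primary) * (k - 1) / max(total - 1, 1)
  for (b in seq_len(n_primary)) {
    parent <- 1L; start <- 0
    for (k in seq_len(split_after)) {
      nid <- nid + 1L
      rows[[length(rows) + 1]] <- data.frame(
        segment_id = nid, parent_id = parent, length_um = seg_length,
        diameter_um = diam_at(k), path_start_um = start,
        path_mid_um = start + seg_length / 2)
      parent <- nid; start <- start + seg_length
    }
    n_rest <- segments_per_branch - split_after
    if (n_rest > 0) {
      n_sec <- if (split_after == 0) 1L else n_secondary
      for (s in seq_len(n_sec)) {
        p2 <- parent; st2 <- start
        for (k in seq_len(n_rest)) {
          nid <- nid + 1L
          rows[[length(rows) + 1]] <- data.frame(
            segment_id = nid, parent_id = p2, length_um = seg_length,
            diameter_um = diam_at(split_after + k), path_start_um = st2,
            path_mid_um = st2 + seg_length / 2)
          p2 <- nid; st2 <- st2 + seg_length
        }
      }
    }
  }
  m <- do.call(rbind, rows)
  rownames(m) <- NULL
  class(m) <- c("morphology", "data.frame")
  m
}

#' @export
print.morphology <- function(x, ...) {
  cat("morphology:", nrow(x) - 1, "dendritic segments,",
      round(sum(x$length_um[-1]), 1), "um total dendrite,",
      "max path distance", round(max(x$path_start_um + x$length_um), 1),
      "um\n")
  invisible(x)
}

# list of ancestor segment ids (excluding self), soma-first
.ancestors <- function(morph) {
  par <- morph$parent_id
  lapply(seq_len(nrow(morph)), function(i) {
    a <- integer(0); p <- par[i]
    while (p > 0) { a <- c(p, a); p <- par[p] }
    a
  })
}

#' Dendritic path distance between points on a morphology
#'
#' Distance along the tree (never Euclidean) between points given as
#' (segment, arc position from the proximal end).
#'
#' @param morph a `morphology`
#' @param seg_a,seg_b segment ids
#' @param pos_a,pos_b arc positions (µm) from the proximal segment end;
#'   vectors are recycled
#' @return numeric vector of path distances (µm)
#' @export
path_distance <- function(morph, seg_a, pos_a, seg_b, pos_b) {
  anc <- .ancestors(morph)
  root_d <- morph$path_start_um
  n <- max(length(seg_a), length(seg_b))
  seg_a <- rep_len(seg_a, n); seg_b <- rep_len(seg_b, n)
  pos_a <- rep_len(pos_a, n); pos_b <- rep_len(pos_b, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    sa <- seg_a[i]; sb <- seg_b[i]
    ra <- root_d[sa] + pos_a[i]; rb <- root_d[sb] + pos_b[i]
    if (sa == sb) { out[i] <- abs(pos_a[i] - pos_b[i]); next }
    if (sa %in% anc[[sb]]) { out[i] <- rb - ra; next }
    if (sb %in% anc[[sa]]) { out[i] <- ra - rb; next }
    common <- intersect(c(anc[[sa]], sa), c(anc[[sb]], sb))
    # deepest common ancestor; both paths pass through its distal end
    lca <- common[which.max(root_d[common])]
    junction <- root_d[lca] + morph$length_um[lca]
    if (lca == 1L) junction <- 0 # soma: dendrites meet at the soma itself
    out[i] <- (ra - junction) + (rb - junction)
  }
  out
}

#' Read / write a morphology as a delimited table
#'
#' Minimal SWC-like format: columns `segment_id`, `parent_id`, `length_um`,
#' `diameter_um`.
#'
#' @param morph a `morphology`
#' @param path file path
#' @return `read_morphology` returns a `morphology`
#' @export
write_morphology <- function(morph, path) {
  utils::write.csv(morph[, c("segment_id", "parent_id", "length_um",
                             "diameter_um")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_morphology
#' @export
read_morphology <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("segment_id", "parent_id", "length_um", "diameter_um")
                %in% names(df)))
  df <- df[order(df$segment_id), ]
  # recompute path distances from tree structure
  df$path_start_um <- 0
  for (i in seq_len(nrow(df))) {
    p <- df$parent_id[i]
    if (p > 1)
      df$path_start_um[i] <- df$path_start_um[p] + df$length_um[p]
  }
  df$path_start_um[df$parent_id == 0] <- 0
  df$path_mid_um <- df$path_start_um + df$length_um / 2
  df$path_mid_um[1] <- 0
  rownames(df) <- NULL
  class(df) <- c("morphology", "data.frame")
  df
}
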