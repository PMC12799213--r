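#' Minimum surface-to-surface distance between two spots
#'
#' Minimum Euclidean distance between boundary voxel centres, in µm; 0 when
#' the voxel masks overlap. Both spots must live on the same voxel grid.
#'
#' @param a,b one-row spot tibbles (from [detect_spots()]) or lists with
#'   elements `boundary` (n x 3 matrix, µm) and optionally `voxels`.
#' @return distance in µm.
#' @export
surface_distance <- function(a, b) {
  va <- spot_field(a, "voxels"); vb <- spot_field(b, "voxels")
  if (!is.null(va) && !is.null(vb) && length(intersect(va, vb))) return(0)
  ba <- spot_field(a, "boundary"); bb <- spot_field(b, "boundary")
  min_pair_distance(ba, bb)
}

spot_field <- function(s, field) {
  v <- s[[field]]
  if (is.list(v) && !is.matrix(v)) v <- v[[1]]
  v
}

min_pair_distance <- function(A, B) {
  # ||a-b||^2 = |a|^2 + |b|^2 - 2 a.b, chunked over A rows
  b2 <- rowSums(B^2)
  best <- Inf
  step <- 2048L
  for (i0 in seq(1L, nrow(A), by = step)) {
    ii <- i0:min(i0 + step - 1L, nrow(A))
    Ai <- A[ii, , drop = FALSE]
    d2 <- outer(rowSums(Ai^2), b2, "+") - 2 * Ai %*% t(B)
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0))
}

#' Classify spots by proximity to a reference set
#'
#' Pairs every query spot with its nearest reference spot when their
#' surface-to-surface distance does not exceed `threshold` (0.06 µm for
#' RIBEYE-Bassoon pairing, 0.045 µm for the +SyRibbon class of CaV1.3
#' clusters). Ties are broken by the smaller reference id.
#'
#' @param query_spots,reference_spots spot tibbles on the same voxel grid.
#' @param threshold pairing distance, µm (>= 0).
#' @return the query tibble with added columns `partner_id` (reference id or
#'   NA), `partner_distance` and logical `colocalized`.
#' @export
classify_by_proximity <- function(query_spots, reference_spots, threshold) {
  if (threshold < 0) abort("`threshold` must be >= 0")
  nq <- nrow(query_spots)
  partner <- rep(NA_integer_, nq)
  dist <- rep(NA_real_, nq)
  if (nq && nrow(reference_spots)) {
    ref_order <- order(reference_spots$id)
    for (i in seq_len(nq)) {
      best <- Inf; best_id <- NA_integer_
      for (j in ref_order) {
        dij <- surface_distance(query_spots[i, ], reference_spots[j, ])
        if (dij < best) { best <- dij; best_id <- reference_spots$id[j] }
      }
      dist[i] <- best
      if (best <= threshold) partner[i] <- best_id
    }
  }
  query_spots |>
    mutate(partner_id = partner, partner_distance = dist,
           colocalized = !is.na(partner))
}

#' Pearson correlation between paired spot volumes
#'
#' Tests whether the volumes of paired puncta co-vary (e.g. larger
#' membrane-anchored Bassoon structures recruiting larger RIBEYE
#' structures).
#'
#' @param paired_spots query tibble from [classify_by_proximity()], with
#'   pairs retained.
#' @param reference_spots the reference tibble providing partner volumes.
#' @return one-row tibble with `estimate` (Pearson r), `p.value` and `n`.
#' @export
volume_correlation <- function(paired_spots, reference_spots) {
  p <- paired_spots |> filter(!is.na(.data$partner_id))
  ref <- reference_spots |> select(partner_id = "id", partner_volume = "volume")
  p <- p |> left_join(ref, by = "partner_id")
  if (nrow(p) < 3) abort("need at least 3 pairs")
  ct <- cor.test(p$volume, p$partner_volume, method = "pearson")
  tibble(estimate = unname(ct$estimate), p.value = ct$p.value, n = nrow(p))
}
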