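# Sham-pair null ensemble and bootstrap masking of twin correlation maps.

#' Enumerate sham (non-co-twin) pairings
#'
#' All unordered pairs of twin individuals minus the true co-twin pairs,
#' optionally restricted to an eligible subject set (e.g. subjects sharing a
#' recording condition or session). With k twin pairs all eligible this
#' yields 2k(k-1) sham pairs.
#'
#' @param twin_pairs data.frame with columns `pair_id`, `member1`,
#'   `member2`.
#' @param eligible optional character vector of eligible subject ids.
#' @return data.frame with columns `member1`, `member2`; zero rows (with a
#'   message) when fewer than two pairs are available.
#' @export
enumerate_sham_pairs <- function(twin_pairs, eligible = NULL) {
  subj <- data.frame(
    id = c(twin_pairs$member1, twin_pairs$member2),
    pair = c(twin_pairs$pair_id, twin_pairs$pair_id),
    stringsAsFactors = FALSE)
  if (!is.null(eligible)) subj <- subj[subj$id %in% eligible, , drop = FALSE]
  if (length(unique(subj$pair)) < 2) {
    message("fewer than two eligible twin pairs: no sham pairings")
    return(data.frame(member1 = character(0), member2 = character(0)))
  }
  n <- nrow(subj)
  out <- list()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (subj$pair[i] != subj$pair[j]) {
      out[[length(out) + 1L]] <- data.frame(member1 = subj$id[i],
                                            member2 = subj$id[j])
    }
  }
  do.call(rbind, out)
}

#' Cellwise mean of twin correlation maps
#'
#' Unweighted mean per (channel, band) across maps; undefined (`NA`) cells
#' are excluded cell by cell.
#'
#' @param maps list of [topo_map()] objects with congruent shapes.
#' @return A [topo_map()] with pair id `"twin_mean"`.
#' @export
twin_mean_map <- function(maps) {
  if (length(maps) < 1) stop("need at least one map")
  dims <- dim(maps[[1]]$R)
  for (m in maps) if (!identical(dim(m$R), dims)) stop("map shapes differ")
  arr <- vapply(maps, function(m) m$R, maps[[1]]$R)
  arr <- array(arr, dim = c(dims, length(maps)))
  R <- apply(arr, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  })
  dimnames(R) <- dimnames(maps[[1]]$R)
  mask <- ifelse(is.na(R), "undefined", "unmasked")
  topo_map("twin_mean", maps[[1]]$condition, R, mask)
}

#' Bootstrap sham-pair masking of a twin-mean correlation map
#'
#' Builds the null distribution of sham-pair mean correlations: for each of
#' `n_boot` replicates, `m` sham maps are drawn (with replacement by
#' default; the same draw is used for every cell, mirroring a selection of
#' m sham *pairs*) and averaged cellwise. Per cell the masking limits are
#' the nearest-rank `alpha` and `1 - alpha` quantiles of the sorted
#' bootstrap means; real values strictly inside `(lo, hi)` are set to zero
#' (masked), values outside are retained. Pre-mask values are preserved
#' bit-exactly in the result's `premask` field.
#'
#' @param real_map the twin-mean [topo_map()].
#' @param sham_maps list of sham [topo_map()] objects (length >= `m`).
#' @param m draw size per replicate (3 for the joint-baseline condition,
#'   8 for meditation/documentary).
#' @param n_boot number of bootstrap replicates (default 1000, >= 100).
#' @param alpha per-tail mask probability (default 0.05).
#' @param seed integer seed; masking is deterministic given it.
#' @param replace draw sham maps with replacement (`FALSE` gives
#'   subsampling semantics).
#' @return List with `map` (masked [topo_map()]), `lo`, `hi` (limit
#'   matrices) and `boot_means` (n_boot x cells matrix).
#' @export
bootstrap_mask <- function(real_map, sham_maps, m, n_boot = 1000,
                           alpha = 0.05, seed = 1L, replace = TRUE) {
  if (n_boot < 100) stop("n_boot must be at least 100")
  S <- length(sham_maps)
  if (m > S) stop("draw size m exceeds the number of sham maps")
  dims <- dim(real_map$R)
  cells <- prod(dims)
  sham_mat <- vapply(sham_maps, function(x) as.vector(x$R), numeric(cells))
  boot <- with_seed(seed, {
    out <- matrix(NA_real_, n_boot, cells)
    for (bidx in seq_len(n_boot)) {
      pick <- sample.int(S, m, replace = replace)
      out[bidx, ] <- rowMeans(sham_mat[, pick, drop = FALSE], na.rm = TRUE)
    }
    out
  })
  lo <- apply(boot, 2, nearest_rank, p = alpha)
  hi <- apply(boot, 2, nearest_rank, p = 1 - alpha)
  lo <- matrix(lo, dims[1], dims[2], dimnames = dimnames(real_map$R))
  hi <- matrix(hi, dims[1], dims[2], dimnames = dimnames(real_map$R))

  R <- real_map$R
  mask <- real_map$mask
  premask <- real_map$R
  inside <- !is.na(R) & R > lo & R < hi
  R[inside] <- 0
  mask[inside] <- "masked_to_zero"
  list(map = topo_map(real_map$pair_id, real_map$condition, R, mask,
                      premask = premask),
       lo = lo, hi = hi, boot_means = boot)
}
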