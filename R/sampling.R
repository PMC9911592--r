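#' Indices falling in a percentile band
#'
#' Empirical, rank-based band selection with no interpolation: index `i` is
#' selected iff `lo < rank_i / N <= hi`, where `rank_i` is the 1-based
#' ascending rank of `values[i]` and ties are broken by stable input order.
#' The default band (0.75, 0.90] keeps the upper range of a score while
#' discarding the extreme top decile as outliers.
#'
#' @param values Numeric vector, length >= 1.
#' @param band Numeric length-2 vector `c(lo, hi)` with `0 <= lo < hi <= 1`.
#' @return Sorted integer indices into `values`; deterministic.
#' @examples
#' percentile_band(1:20, c(0.75, 0.90))  # 16 17 18
#' @export
percentile_band <- function(values, band = c(0.75, 0.90)) {
  if (!length(values)) {
    abort("cannot take a percentile band of an empty vector",
          class = "alextract_param_error")
  }
  if (length(band) != 2 || band[1] < 0 || band[2] > 1 || band[1] >= band[2]) {
    abort("band must be c(lo, hi) with 0 <= lo < hi <= 1",
          class = "alextract_param_error")
  }
  n <- length(values)
  r <- integer(n)
  r[order(values)] <- seq_len(n)  # stable: ties keep input order
  q <- r / n
  which(q > band[1] & q <= band[2])
}

#' Strategic percentile-band batch selection
#'
#' The strategic acquisition rule: candidate sentences are those lying in
#' the percentile band of *both* pseudo-perplexity and sentence length (the
#' intersection of the two one-dimensional bands — the strictest reading of
#' selecting on "the perplexity scores and sentence lengths"; `combine`
#' offers the union and sequential-filter variants). From the candidates,
#' `batch_size` sentences are drawn uniformly without replacement under the
#' seed. If the candidates cannot fill the batch, the remainder is drawn
#' from the union of the two bands, then from the full pool (a fallback
#' ladder recorded in the result's `"fallback"` attribute).
#'
#' @param scores Tibble from [score_pool()] (`sent_id`, `length`, `ppl`).
#' @param band Percentile band, default `c(0.75, 0.90)`.
#' @param batch_size Number of sentences to select (>= 1).
#' @param seed Integer seed.
#' @param combine How to combine the two bands: `"intersection"` (default),
#'   `"union"`, or `"ppl_then_length"` (band over ppl, then band over length
#'   within it).
#' @return Character vector of selected `sent_id`s with attribute
#'   `"fallback"` (`"intersection"`, `"union"` or `"pool"` — the deepest
#'   ladder level used).
#' @export
strategic_sample <- function(scores, band = c(0.75, 0.90), batch_size,
                             seed = 1L,
                             combine = c("intersection", "union",
                                         "ppl_then_length")) {
  combine <- match.arg(combine)
  if (!nrow(scores)) {
    abort("cannot sample from an empty pool", class = "alextract_param_error")
  }
  if (batch_size < 1) {
    abort("batch_size must be >= 1", class = "alextract_param_error")
  }
  ppl_idx <- percentile_band(scores$ppl, band)
  len_idx <- percentile_band(scores$length, band)
  cand <- switch(combine,
    intersection = intersect(ppl_idx, len_idx),
    union = union(ppl_idx, len_idx),
    ppl_then_length = {
      sub <- scores$length[ppl_idx]
      if (length(sub)) ppl_idx[percentile_band(sub, band)] else integer()
    }
  )
  cand <- sort(cand)
  union_idx <- sort(union(ppl_idx, len_idx))
  pool_idx <- seq_len(nrow(scores))

  resample <- function(x, k) x[sample.int(length(x), k)]
  withr::with_seed(seed, {
    if (length(cand) >= batch_size) {
      pick <- sort(resample(cand, batch_size))
      fallback <- "intersection"
    } else {
      pick <- cand
      extra <- setdiff(union_idx, pick)
      need <- batch_size - length(pick)
      if (length(extra) >= need) {
        pick <- sort(c(pick, resample(extra, need)))
        fallback <- "union"
      } else {
        pick <- c(pick, extra)
        rest <- setdiff(pool_idx, pick)
        need <- min(batch_size - length(pick), length(rest))
        pick <- sort(c(pick, if (need > 0) resample(rest, need) else integer()))
        fallback <- "pool"
      }
    }
  })
  out <- scores$sent_id[pick]
  attr(out, "fallback") <- fallback
  out
}

#' Random batch selection
#'
#' Uniform sampling without replacement from the unlabeled pool,
#' reproducible under the seed; the random-acquisition baseline.
#'
#' @param pool Character vector of sentence ids (or a tibble with
#'   `sent_id`).
#' @param batch_size Number to draw; must not exceed the pool size.
#' @param seed Integer seed.
#' @return Character vector of selected ids.
#' @export
random_sample <- function(pool, batch_size, seed = 1L) {
  ids <- if (is.data.frame(pool)) pool$sent_id else pool
  if (batch_size > length(ids)) {
    abort(sprintf("batch_size (%d) exceeds pool size (%d)",
                  batch_size, length(ids)),
          class = "alextract_param_error")
  }
  withr::with_seed(seed, sample(ids, batch_size))
}
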