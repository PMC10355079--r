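# build a 5-min activity record stream from per-hour score vectors
# scores: list of integer vectors (length <= 12), one per consecutive hour;
# NA entries are dropped (missing records)
hour_records <- function(scores, start = as.POSIXct("2019-08-01 00:00:00",
                                                    tz = "UTC")) {
  out <- do.call(rbind, lapply(seq_along(scores), function(h) {
    s <- scores[[h]]
    t <- start + (h - 1) * 3600 + 300 * (seq_along(s) - 1)
    data.frame(timestamp_utc = t, score = s, n_subsamples = 5L)
  }))
  out <- out[!is.na(out$score), ]
  rownames(out) <- NULL
  out
}

# a constant block of 5-min records
block_records <- function(score, n, start) {
  data.frame(timestamp_utc = start + 300 * (seq_len(n) - 1),
             score = score, n_subsamples = 5L)
}
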