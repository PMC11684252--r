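## independent brute-force oracle for coverage: a daily "pill stock"
## simulation, deliberately separate from the package's interval
## arithmetic (and from the generator's internal truth computation)
oracle_covered_days <- function(fill_offsets, days_supply, window_len) {
  stock <- 0
  covered <- 0L
  for (d in 0:(window_len - 1L)) {
    stock <- stock + sum(days_supply[fill_offsets == d])
    if (stock > 0) {
      covered <- covered + 1L
      stock <- stock - 1
    }
  }
  covered
}

## random fill pattern used by the oracle-equivalence properties
random_fill_case <- function() {
  wl <- sample(30:365, 1)
  k <- sample(1:20, 1)
  offs <- sort(sample(0:(wl - 1), k, replace = TRUE))
  ds <- sample(7:90, k, replace = TRUE)
  list(wl = wl, offs = offs, ds = ds)
}

fills_from_case <- function(case, index = as.Date("2021-01-01")) {
  list(window = list(index_date = index,
                     end_date = index + case$wl - 1L),
       fills = data.frame(fill_date = index + case$offs,
                          days_supply = case$ds))
}
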