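# Independent oracles, deliberately implemented apart from the package code.

# exact decimal half-up rounding of k/T to 2 decimals, in integer hundredths
oracle_main_cents <- function(k, T) {
  q <- (100L * k) %/% T
  rem <- (100L * k) %% T
  q + as.integer(2L * rem >= T)
}

# direct index evaluation on a binary row split per main indicator:
# sum of per-main mean scores, each half-up rounded at 2 decimals
oracle_pmc <- function(bits_by_main) {
  cents <- vapply(bits_by_main, function(b)
    oracle_main_cents(sum(b), length(b)), integer(1))
  sum(cents) / 100
}

# brute-force competition rank: 1 + number of strictly greater values
oracle_rank <- function(x) {
  vapply(x, function(v) 1L + sum(x > v), integer(1))
}

# random small schema: up to max_mains mains with 0..max_subs subs each
random_schema <- function(max_mains = 4, max_subs = 5) {
  n_mains <- sample.int(max_mains, 1)
  mains <- lapply(seq_len(n_mains), function(t) {
    n_subs <- sample(0:max_subs, 1)
    list(id = paste0("X", t), label = paste("main", t), source = "",
         subs = lapply(seq_len(n_subs), function(j)
           list(id = paste0("X", t, ":", j), label = paste("sub", t, j),
                source_note = "")))
  })
  s <- structure(list(name = "random", version = "0", mains = mains),
                 class = "pmc_schema")
  validate_schema(s)
  s
}

# random binary score matrix for a schema
random_matrix <- function(schema, n = 5) {
  ids <- binary_ids(schema)
  m <- tibble::tibble(pid = paste0("P", seq_len(n)))
  for (id in ids) m[[id]] <- sample(0:1, n, replace = TRUE)
  m
}

# split a matrix row into per-main binary vectors (including implicit vars)
split_row <- function(m, schema, i) {
  lapply(schema$mains, function(main) {
    ids <- if (length(main$subs) == 0) main$id
           else vapply(main$subs, `[[`, character(1), "id")
    as.integer(unlist(m[i, ids]))
  })
}

# brute-force all-pairs document co-occurrence counter
oracle_cooccurrence <- function(token_lists) {
  counts <- list()
  for (toks in token_lists) {
    u <- sort(unique(toks))
    if (length(u) < 2) next
    for (i in seq_len(length(u) - 1)) for (j in (i + 1):length(u)) {
      key <- paste(u[i], u[j], sep = "|")
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a
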