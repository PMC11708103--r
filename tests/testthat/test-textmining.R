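test_that("tokenizer segments, normalizes and filters", {
  expect_equal(tokenize("emergency response emergency team", min_chars = 1),
               c("emergency", "response", "emergency", "team"))
  expect_equal(
    tokenize("emergency response emergency team", stopwords = "response"),
    c("emergency", "emergency", "team"))
  expect_equal(tokenize("Emergency TEAM; a x"), c("emergency", "team"))
  # single-character noise dropped by default, kept with min_chars = 1
  expect_equal(tokenize("a b cd", min_chars = 1), c("a", "b", "cd"))
  expect_equal(tokenize("a b cd"), "cd")
  # pluggable segmenters
  expect_equal(tokenize("abc", segmenter = "character", min_chars = 1),
               c("a", "b", "c"))
  rev_seg <- function(x) rev(strsplit(x, " ")[[1]])
  expect_equal(tokenize("one two", segmenter = rev_seg), c("two", "one"))
  expect_error(tokenize("x", segmenter = "nope"), "unknown segmenter")
  expect_error(tokenize("   "), "empty")
})

test_that("planted token frequencies are recovered exactly", {
  planted <- c(rep("emergency", 10), rep("team", 4), rep("law", 1))
  withr::with_seed(3, txt <- paste(sample(planted), collapse = " "))
  toks <- tokenize(txt)
  expect_equal(sort(c(table(toks)), decreasing = TRUE),
               sort(c(table(planted)), decreasing = TRUE))
})

test_that("top_terms sorts by count with lexicographic ties and prefix property", {
  corpus <- tibble::tibble(
    pid = c("P1", "P2"),
    text = c("emergency emergency team zebra", "emergency team apple zebra"))
  tt <- top_terms(corpus, 10, min_chars = 1)
  expect_equal(tt$term[1], "emergency")
  expect_equal(tt$count[1], 3L)
  expect_equal(tt$doc_freq[1], 2L)
  # team (2) and zebra (2) tie -> lexicographic
  expect_equal(tt$term[2:3], c("team", "zebra"))
  # prefix property
  for (n in 1:4) expect_equal(top_terms(corpus, n), tt[seq_len(n), ])
  expect_error(top_terms(corpus, 0), "positive")

  single <- tibble::tibble(pid = "P1", text = "word word word")
  one <- top_terms(single, 1)
  expect_equal(one$term, "word")
  expect_equal(one$count, 3L)
})

test_that("document co-occurrence counts shared documents", {
  corpus <- tibble::tibble(pid = "P1", text = "aa bb")
  g <- cooccurrence(corpus)
  expect_equal(g$term_a, "aa")
  expect_equal(g$term_b, "bb")
  expect_equal(g$weight, 1L)

  corpus <- tibble::tibble(pid = c("P1", "P2", "P3"),
                           text = c("aa bb", "aa bb", "aa cc"))
  g <- cooccurrence(corpus)
  expect_equal(g$weight[g$term_a == "aa" & g$term_b == "bb"], 2L)
  expect_equal(g$weight[g$term_a == "aa" & g$term_b == "cc"], 1L)
  # no self-loops, canonical ordering (undirected symmetry)
  expect_true(all(g$term_a < g$term_b))
  expect_error(cooccurrence(corpus, window = 0), "positive")
})

test_that("co-occurrence weights match a brute-force all-pairs oracle", {
  cfg <- generator_config(n_policies = 8, seed = 17, doc_length = 30)
  corpus <- gen_corpus(cfg)
  g <- cooccurrence(corpus)
  toks <- lapply(corpus$text, tokenize)
  expected <- oracle_cooccurrence(toks)
  expect_equal(nrow(g), length(expected))
  for (i in seq_len(nrow(g))) {
    key <- paste(g$term_a[i], g$term_b[i], sep = "|")
    expect_equal(g$weight[i], expected[[key]])
  }
})

test_that("sliding-window co-occurrence counts qualifying windows", {
  corpus <- tibble::tibble(pid = "P1", text = "aa bb cc aa")
  g <- cooccurrence(corpus, window = 2)
  # windows: (aa,bb) (bb,cc) (cc,aa)
  w <- function(a, b) g$weight[g$term_a == a & g$term_b == b]
  expect_equal(w("aa", "bb"), 1L)
  expect_equal(w("bb", "cc"), 1L)
  expect_equal(w("aa", "cc"), 1L)
  # window longer than the document degrades to whole-document
  g2 <- cooccurrence(corpus, window = 10)
  expect_equal(w("aa", "bb"), 1L)
})

test_that("removing a document never increases counts or weights", {
  cfg <- generator_config(n_policies = 6, seed = 5, doc_length = 40)
  corpus <- gen_corpus(cfg)
  full_tt <- top_terms(corpus, 100)
  full_g <- cooccurrence(corpus)
  sub_tt <- top_terms(corpus[-3, ], 100)
  sub_g <- cooccurrence(corpus[-3, ])
  for (i in seq_len(nrow(sub_tt))) {
    j <- match(sub_tt$term[i], full_tt$term)
    expect_lte(sub_tt$count[i], full_tt$count[j])
  }
  for (i in seq_len(nrow(sub_g))) {
    j <- which(full_g$term_a == sub_g$term_a[i] &
               full_g$term_b == sub_g$term_b[i])
    expect_lte(sub_g$weight[i], full_g$weight[j])
  }
})

test_that("corpus directory round-trip and graph export", {
  dir <- withr::local_tempdir()
  writeLines("emergency team", file.path(dir, "P1.txt"))
  writeLines("emergency law", file.path(dir, "P2.txt"))
  corpus <- read_corpus(dir)
  expect_equal(corpus$pid, c("P1", "P2"))
  g <- cooccurrence(corpus)
  csv <- file.path(dir, "edges.csv")
  gml <- file.path(dir, "graph.graphml")
  write_cooccurrence(g, csv = csv, graphml = gml)
  edges <- utils::read.csv(csv)
  expect_equal(nrow(edges), nrow(g))
  expect_equal(sort(names(edges)), c("source", "target", "weight"))
  ig <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(ig), nrow(g))
  expect_error(read_corpus(file.path(dir, "missing")), "not found")
})
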