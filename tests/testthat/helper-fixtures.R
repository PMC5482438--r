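# Shared fixtures: bundled worked-example annotations, a bracketed parse for
# the sodium sentence, and a generator of random synthetic segments.

fixture_path <- function(name) {
  system.file("extdata", "fixtures", name, package = "dietner")
}

sodium_annotation <- function() {
  read_fixture_annotation(
    fixture_path("sodium_sentence.tsv"),
    text = paste("People of any age who are African Americans should",
                 "further reduce sodium intake to 300 mg per day."))
}

fiber_annotation <- function() {
  read_fixture_annotation(
    fixture_path("fiber_sentence.tsv"),
    text = paste("The recommended intake for total fiber for adults 50 years",
                 "and younger is set at 38 g for men and 25 g for women,",
                 "while for men and women over 50 it is 30 g and 21 g per",
                 "day, respectively, due to decreased food consumptions."))
}

sodium_parse_tree <- function() {
  read_parse_tree(paste(readLines(fixture_path("sodium_sentence_parse_synthetic.txt")),
                        collapse = " "))
}

# Fifteen recommendation sentences used as a segmentation corpus.
fifteen_recommendations <- c(
  "Good sources of magnesium are: fruits or vegetables, nuts, peas and beans, soy products, whole grains and milk.",
  "The RDAs for Mg are 300 mg for young women and 350 mg for young men.",
  "Increase potassium by ordering a salad, extra steamed or roasted vegetables, bean-based dishes fruit salads, and low-fat milk instead of soda.",
  "Babies need protein about 10 g a day.",
  "1 teaspoon of table salt contains 2300 mg of sodium.",
  "Milk, cheese, yogurt and other dairy products are good sources of calcium and protein, plus many other vitamins and minerals.",
  "Breast milk provides sufficient zinc, 2 mg/day for the first 4-6 months of life.",
  "If you're trying to get more omega-3, you might choose salmon, tuna, or eggs enriched with omega-3.",
  "If you need to get more fiber, look to beans, vegetables, nuts and legumes.",
  "Eating foods high in vitamin C and iron can reduce the absorption of ingested nickel.",
  "The body of a 76 kg man contains about 12 kg of protein.",
  "Excellent sources of alpha-linolenic acid, ALA, include flaxseeds and walnuts.",
  "The recommended intake for total fiber for adults 50 years and younger is set at 38 g for men and 25 g for women, while for men and women over 50 it is 30 g and 21 g per day, respectively, due to decreased food consumption.",
  "I'm good at tennis.",
  "Your hat looks very nice."
)

# Text normalization used when comparing segment text to reference sentences:
# case-insensitive, trailing sentence punctuation ignored.
norm_text <- function(x) {
  x <- tolower(x)
  x <- gsub("\\s*[.]\\s*$", "", x)
  gsub("\\s+", " ", trimws(x))
}

# Random synthetic segment: a valid random B-I-O annotation over a small
# vocabulary that includes dictionary terms, so entity mentions arise.
random_segment <- function(n_target = 12, with_triggers = FALSE) {
  vocab <- c("people", "intake", "amount", "level", "diet", "value", "men",
             "women", "adults", "sodium", "fiber", "protein", "milk", "salt",
             "mg", "g", "teaspoon", "day", "while", "and", ",", "study")
  pos_pool <- c("NN", "NNS", "JJ", "CD", "DT", "IN", "VBZ", "VB", "RB", "WP")
  types <- c("NP", "NP", "NP", "VP", "PP", "O")
  if (with_triggers) types <- c(types, "ADVP", "O")
  token <- character(0); pos <- character(0); chunk <- character(0)
  while (length(token) < n_target) {
    tp <- sample(types, 1)
    len <- if (tp %in% c("O", "PP", "ADVP")) 1L else sample(1:3, 1)
    for (j in seq_len(len)) {
      token <- c(token, sample(vocab, 1))
      pos <- c(pos, sample(pos_pool, 1))
      chunk <- c(chunk, if (tp == "O") "O" else paste0(if (j == 1) "B-" else "I-", tp))
    }
  }
  new_annotated_sentence(token, pos, chunk)
}

# Independent span scanner used as the oracle for the token-by-chunk matrix:
# walks the tags once, assigning a running chunk id.
oracle_chunk_matrix <- function(chunk_tags) {
  n <- length(chunk_tags)
  id <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!startsWith(chunk_tags[i], "I-")) cur <- cur + 1L
    id[i] <- cur
  }
  x <- matrix(0L, n, cur)
  for (i in seq_len(n)) x[i, id[i]] <- 1L
  x
}

# TRUE iff `sub` appears within `full` in order (not necessarily contiguous).
is_subsequence <- function(sub, full) {
  j <- 1L
  for (x in sub) {
    while (j <= length(full) && full[j] != x) j <- j + 1L
    if (j > length(full)) return(FALSE)
    j <- j + 1L
  }
  TRUE
}

# Conjunction-of-pairwise-functions form of the merge guard: enumerates all
# ordered pairs of distinct entity types and ANDs the pairwise !(A & B)
# functions together.
oracle_merge_guard <- function(a, b) {
  k <- length(a)
  pairs <- expand.grid(e1 = seq_len(k), e2 = seq_len(k))
  pairs <- pairs[pairs$e1 != pairs$e2, ]
  all(mapply(function(e1, e2) !(a[e1] == 1 && b[e2] == 1), pairs$e1, pairs$e2))
}
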