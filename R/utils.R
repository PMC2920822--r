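`%||%` <- function(a, b) if (is.null(a)) b else a

## Natural chromosome ordering: 1..22 numerically, then X, Y, MT, then
## anything else alphabetically.  Tolerates a "chr" prefix.
chrom_rank <- function(chr) {
  key <- sub("^chr", "", as.character(chr), ignore.case = TRUE)
  num <- suppressWarnings(as.numeric(key))
  rank <- ifelse(!is.na(num), num,
                 ifelse(toupper(key) == "X", 1e3,
                        ifelse(toupper(key) == "Y", 1e3 + 1,
                               ifelse(toupper(key) %in% c("M", "MT"), 1e3 + 2, NA))))
  if (anyNA(rank)) {
    other <- sort(unique(key[is.na(rank)]))
    rank[is.na(rank)] <- 2e3 + match(key[is.na(rank)], other)
  }
  rank
}

## Deterministic 31-bit seed derived from a root seed and a node path string.
## Polynomial string hash folded into the root seed; always in [1, 2^31 - 2]
## so it is a valid R integer seed.
derive_seed <- function(root_seed, path) {
  mod <- 2147483647
  h <- as.double(root_seed %% mod)
  for (code in utf8ToInt(as.character(path))) {
    h <- (h * 31 + code) %% mod
  }
  as.integer(h %% (mod - 1) + 1)
}

## Compact deterministic hash of a +/-1 label vector (FNV-1a over bytes),
## used for cycle detection bookkeeping in the alternating MMC loop.
hash_labels <- function(labels) {
  h <- 2166136261
  for (b in as.integer(labels > 0)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == as.integer(x) && x >= min
}

is_scalar_num <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x)
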