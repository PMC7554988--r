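# Independent oracles used to cross-check the package implementations.
# These are deliberately naive (explicit loops, exhaustive recursion) and
# share no code with the implementation paths they verify.

# Brute-force O(n^2) contact scan: explicit double loop over atoms.
oracle_contact_residues <- function(struct, chainA, chainB, cutoff = 4.0) {
  a <- atoms(struct)
  a <- a[a$elesy != "H", ]
  A <- a[a$chain == chainA & !a$hetero, ]
  B <- a[a$chain == chainB & !a$hetero, ]
  resA <- integer(0); resB <- integer(0)
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      d <- sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2 +
                  (A$z[i] - B$z[j])^2)
      if (d < cutoff) {
        resA <- c(resA, A$resno[i])
        resB <- c(resB, B$resno[j])
      }
    }
  }
  list(a = sort(unique(resA)), b = sort(unique(resB)))
}

# Exhaustive affine-gap global alignment score by recursion over all
# paths (no memoisation): a gap of length L costs open + extend * L.
oracle_global_score <- function(a, b, mat, open, extend) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  na <- length(A); nb <- length(B)
  rec <- function(i, j, prev) {
    if (i > na && j > nb) return(0)
    best <- -Inf
    if (i <= na && j <= nb)
      best <- max(best, mat[A[i], B[j]] + rec(i + 1L, j + 1L, "M"))
    if (i <= na) {  # gap in B (consume A)
      cost <- extend + if (prev == "GB") 0 else open
      best <- max(best, -cost + rec(i + 1L, j, "GB"))
    }
    if (j <= nb) {  # gap in A (consume B)
      cost <- extend + if (prev == "GA") 0 else open
      best <- max(best, -cost + rec(i, j + 1L, "GA"))
    }
    best
  }
  rec(1L, 1L, "M")
}

# hand tally of one alignment column
oracle_column_tally <- function(msa, j) {
  chars <- vapply(as.character(msa), function(s) substr(s, j, j), "")
  table(chars)
}

random_aa <- function(n) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"), n,
               replace = TRUE), collapse = "")
}

blosum62 <- function() FeSConserv:::.blosum62()
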