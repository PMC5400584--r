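# Progressive multiple alignment for small domain families.
#
# Pairwise identity distances (Biostrings global alignments) feed an
# average-linkage guide tree; profiles are merged bottom-up with a
# profile-profile Needleman-Wunsch using expected BLOSUM62 column scores
# and a linear gap penalty. The output is a valid family MSA (rows ungap
# to their inputs); it makes no claim of matching any particular external
# aligner's output.

#' Align the member sequences of a domain family
#'
#' @param seqs Named character vector of ungapped domain sequences
#'   (names are instance ids). A single sequence yields the trivial
#'   one-row alignment.
#' @param method `"builtin"` for the bundled progressive aligner,
#'   `"external"` to shell out to `mafft` (must be on the PATH).
#' @param gap Linear gap penalty (builtin aligner), a positive number.
#' @param family_id Optional family id to attach to the result.
#' @return A `domain_msa`.
#' @export
align_family <- function(seqs, method = c("builtin", "external"),
                         gap = 6, family_id = NA_character_) {
  method <- match.arg(method)
  if (length(seqs) == 0) abort("cannot align an empty family")
  if (any(nchar(seqs) == 0)) abort("cannot align empty sequences")
  if (length(seqs) == 1) {
    return(new_msa(seqs, family_id))
  }
  rows <- switch(method,
                 builtin = align_progressive(seqs, gap),
                 external = align_mafft(seqs))
  msa <- new_msa(rows[names(seqs)], family_id)
  stopifnot(identical(gsub("-", "", as.character(msa), fixed = TRUE),
                      as.character(seqs)))
  msa
}

align_mafft <- function(seqs) {
  if (Sys.which("mafft") == "") abort("mafft not found on the PATH")
  fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(fin, fout)))
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), fin)
  status <- system2("mafft", c("--quiet", "--auto", fin),
                    stdout = fout, stderr = FALSE)
  if (status != 0) abort("mafft failed")
  set <- Biostrings::readBStringSet(fout)
  setNames(toupper(as.character(set)), sub("\\s.*$", "", names(set)))
}

align_progressive <- function(seqs, gap) {
  n <- length(seqs)
  if (n == 2) {
    prof <- profile_align(seq_profile(seqs[1]), seq_profile(seqs[2]), gap)
    return(profile_rows(prof))
  }
  # guide tree from pairwise percent-identity distances
  d <- matrix(0, n, n)
  sub <- blosum62_matrix()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pa <- Biostrings::pairwiseAlignment(
        seqs[[i]], seqs[[j]], type = "global",
        substitutionMatrix = sub, gapOpening = 10, gapExtension = 0.5)
      d[i, j] <- d[j, i] <- 1 - Biostrings::pid(pa) / 100
    }
  }
  tree <- hclust(as.dist(d), method = "average")
  profiles <- purrr::imap(as.list(seqs), function(s, nm) {
    seq_profile(setNames(s, nm))
  })
  merged <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    pick <- function(idx) {
      if (idx < 0) profiles[[-idx]] else merged[[idx]]
    }
    merged[[step]] <- profile_align(pick(tree$merge[step, 1]),
                                    pick(tree$merge[step, 2]), gap)
  }
  profile_rows(merged[[n - 1]])
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# A profile is a list(rows = named character vector of gapped strings,
# mat = L x 20 matrix of per-column amino-acid frequencies).
seq_profile <- function(s) {
  chars <- strsplit(unname(s), "")[[1]]
  mat <- matrix(0, length(chars), length(AA_STANDARD),
                dimnames = list(NULL, AA_STANDARD))
  known <- chars %in% AA_STANDARD
  mat[cbind(which(known), match(chars[known], AA_STANDARD))] <- 1
  list(rows = setNames(unname(s), names(s)), mat = mat)
}

profile_rows <- function(prof) prof$rows

# Expected substitution score between two profile columns under BLOSUM62;
# unknown residues (X) contribute zero.
profile_align <- function(pa, pb, gap) {
  B <- blosum62_matrix()[AA_STANDARD, AA_STANDARD]
  S <- pa$mat %*% B %*% t(pb$mat)   # La x Lb expected scores
  la <- nrow(S); lb <- ncol(S)
  F <- matrix(0, la + 1, lb + 1)
  F[, 1] <- -gap * (0:la)
  F[1, ] <- -gap * (0:lb)
  ptr <- matrix(0L, la + 1, lb + 1)  # 1 diag, 2 up (gap in b), 3 left
  ptr[, 1] <- 2L; ptr[1, ] <- 3L; ptr[1, 1] <- 0L
  for (i in seq_len(la)) {
    diag_s <- F[i, 1:lb] + S[i, ]
    up_col <- F[i, 2:(lb + 1)] - gap
    # row-wise fill: left moves depend on already-filled cells of row i+1
    row_new <- numeric(lb)
    prev <- F[i + 1, 1]
    for (j in seq_len(lb)) {
      best <- diag_s[j]; who <- 1L
      if (up_col[j] > best) { best <- up_col[j]; who <- 2L }
      left <- prev - gap
      if (left > best) { best <- left; who <- 3L }
      row_new[j] <- best; prev <- best
      ptr[i + 1, j + 1] <- who
    }
    F[i + 1, 2:(lb + 1)] <- row_new
  }
  # traceback
  i <- la; j <- lb
  ops <- integer(0)
  while (i > 0 || j > 0) {
    who <- if (i == 0) 3L else if (j == 0) 2L else ptr[i + 1, j + 1]
    ops <- c(who, ops)
    if (who == 1L) { i <- i - 1; j <- j - 1 }
    else if (who == 2L) i <- i - 1
    else j <- j - 1
  }
  take_a <- ops != 3L   # columns consuming a position of profile a
  take_b <- ops != 2L
  L <- length(ops)
  expand <- function(prof, take) {
    idx <- integer(L); idx[take] <- seq_len(nrow(prof$mat))
    rows <- vapply(prof$rows, function(r) {
      ch <- strsplit(r, "")[[1]]
      out <- rep("-", L); out[take] <- ch
      paste(out, collapse = "")
    }, "")
    mat <- matrix(0, L, length(AA_STANDARD),
                  dimnames = list(NULL, AA_STANDARD))
    mat[take, ] <- prof$mat
    list(rows = rows, mat = mat)
  }
  ea <- expand(pa, take_a); eb <- expand(pb, take_b)
  na <- length(pa$rows); nb <- length(pb$rows)
  list(rows = c(ea$rows, eb$rows),
       mat = (na * ea$mat + nb * eb$mat) / (na + nb))
}
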