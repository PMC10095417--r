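# Shared fixtures and independent oracle implementations used to cross-check
# the package's operations. The oracles are deliberately naive (line-by-line
# parsing, exhaustive enumeration) and share no code with the implementation.

NISIN_S <- "ITSYSLCTPGCKTGALMGCTMKTASCGCHVHISK"
NISIN_A <- "ITSISLCTPGCKTGALMGCNMKTATCHCSIHVSK"
NISIN_F <- "ITSISLCTPGCKTGALMGCNMKTATCHCSVHVSK"

AA20 <- c("G","A","S","P","V","T","C","L","I","N",
          "D","Q","K","E","M","H","F","R","Y","W")

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")
random_dna <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE), collapse = "")

# -- independent FASTA parser (accumulating line reader) ---------------------
oracle_parse_fasta <- function(path) {
  lines <- readLines(path)
  ids <- character(0); seqs <- character(0)
  cur <- NULL; buf <- ""
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      if (!is.null(cur)) { ids <- c(ids, cur); seqs <- c(seqs, buf) }
      cur <- sub("\\s.*$", "", substring(ln, 2))
      buf <- ""
    } else {
      buf <- paste0(buf, toupper(trimws(ln)))
    }
  }
  if (!is.null(cur)) { ids <- c(ids, cur); seqs <- c(seqs, buf) }
  data.frame(identifier = ids, residues = seqs)
}

# -- brute-force six-frame ORF scan ------------------------------------------
oracle_revcomp <- function(seq) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

oracle_orfs <- function(seq, min_len) {
  L <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else oracle_revcomp(seq)
    for (frame in 0:2) {
      n <- (nchar(s) - frame) %/% 3
      if (n < 2) next
      pos <- frame + 1 + 3 * (seq_len(n) - 1)
      codons <- substring(s, pos, pos + 2)
      for (i in seq_len(n)) {
        if (!codons[i] %in% c("ATG", "GTG", "TTG")) next
        for (j in i:n) {
          if (codons[j] %in% c("TAA", "TAG", "TGA")) {
            if (j - i >= min_len) {
              nt0 <- frame + 3 * (i - 1); nt1 <- frame + 3 * j
              coords <- if (strand == "+") c(nt0, nt1) else c(L - nt1, L - nt0)
              out[[length(out) + 1]] <-
                data.frame(start = coords[1], end = coords[2], strand = strand)
            }
            break # nearest stop only: no read-through
          }
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(0), end = integer(0), strand = character(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$end, df$strand), , drop = FALSE]
}

# -- brute-force tryptic digest ----------------------------------------------
oracle_digest <- function(seq, max_missed) {
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  sites <- which(chars[-n] %in% c("K", "R") & chars[-1] != "P")
  is_boundary <- function(p) p == 0 || p == n || p %in% sites
  out <- list()
  for (a in 1:n) {
    for (b in a:n) {
      if (!is_boundary(a - 1) || !is_boundary(b)) next
      internal <- sum(sites >= a & sites < b)
      if (internal <= max_missed) {
        out[[length(out) + 1]] <- data.frame(
          sequence = substring(seq, a, b), start = a, end = b,
          missed_cleavages = internal
        )
      }
    }
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$end - df$start), , drop = FALSE]
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# additive 4-taxon metric from the tree ((A:1,B:2):1.5,C:3,D:4); in an
# unrooted view the internal edge has length 1.5
additive_4taxon <- function() {
  d <- matrix(0, 4, 4, dimnames = list(c("A","B","C","D"), c("A","B","C","D")))
  d["A","B"] <- d["B","A"] <- 1 + 2
  d["A","C"] <- d["C","A"] <- 1 + 1.5 + 3
  d["A","D"] <- d["D","A"] <- 1 + 1.5 + 4
  d["B","C"] <- d["C","B"] <- 2 + 1.5 + 3
  d["B","D"] <- d["D","B"] <- 2 + 1.5 + 4
  d["C","D"] <- d["D","C"] <- 3 + 4
  d
}
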