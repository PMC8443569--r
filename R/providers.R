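#' Deterministic stub feature providers
#'
#' Per-residue feature providers normally backed by external predictors (PSSM
#' from iterative sequence search, 3-class secondary structure, intrinsic
#' disorder scores). The stub providers generate well-formed surrogate features
#' as a pure function of (sequence, seed): PSSM rows are normalized positive
#' draws (Dirichlet-like, rows sum to 1), secondary structure follows a sticky
#' 3-state Markov chain over \{H, E, C\}, and the three disorder tracks are
#' smoothed uniform noise clamped to [0, 1]. They carry no biology; they exist
#' so every downstream stage runs without external binaries.
#'
#' @param seed integer; combined with a hash of each sequence, so the same
#'   (sequence, seed) always yields identical features.
#' @return A list of class `pepnet_providers` with functions `pssm(seq)`
#'   (n x 20 matrix in [0,1]), `ss(seq)` (string over H/E/C), and
#'   `disorder(seq)` (n x 3 matrix in [0,1]).
#' @examples
#' pv <- stub_feature_providers(seed = 1)
#' pv$ss("ACDEFGHIK")
#' @export
stub_feature_providers <- function(seed = 1L) {
  seed <- as.integer(seed)
  pssm <- function(seq) {
    n <- nchar(seq)
    with_seed(string_hash(paste0("pssm:", seq), seed), {
      m <- matrix(-log(stats::runif(n * 20)), nrow = n, ncol = 20)
      m / rowSums(m)
    })
  }
  ss <- function(seq) {
    n <- nchar(seq)
    states <- c("H", "E", "C")
    with_seed(string_hash(paste0("ss:", seq), seed), {
      s <- integer(n)
      s[1] <- sample.int(3, 1)
      if (n > 1) {
        for (i in 2:n) {
          stay <- stats::runif(1) < 0.8
          s[i] <- if (stay) s[i - 1] else sample(setdiff(1:3, s[i - 1]), 1)
        }
      }
      paste(states[s], collapse = "")
    })
  }
  disorder <- function(seq) {
    n <- nchar(seq)
    with_seed(string_hash(paste0("dis:", seq), seed), {
      raw <- matrix(stats::runif(n * 3), nrow = n, ncol = 3)
      if (n >= 3) {
        sm <- apply(raw, 2, function(col) {
          f <- stats::filter(col, rep(1 / 3, 3), sides = 2)
          f[is.na(f)] <- col[is.na(f)]
          as.numeric(f)
        })
        raw <- matrix(sm, nrow = n, ncol = 3)
      }
      pmin(pmax(raw, 0), 1)
    })
  }
  structure(list(pssm = pssm, ss = ss, disorder = disorder, kind = "stub",
                 seed = seed),
            class = "pepnet_providers")
}

#' File-backed feature providers
#'
#' Reads pre-computed features through a manifest TSV mapping sequence id to
#' feature file paths: PSSM as whitespace-delimited n x 20 numeric text,
#' secondary structure as a single-line H/E/C string, disorder as an n x 3 TSV
#' (no header). Sequences without a manifest row fall back to the stub
#' providers.
#'
#' @param manifest path to a TSV with columns `id`, `pssm`, `ss`, `disorder`
#'   (file paths, relative to the manifest's directory or absolute; `-` for
#'   absent).
#' @param sequences named character vector mapping id to sequence, used to look
#'   up the manifest row for a given sequence.
#' @param fallback providers used when an id or file is absent.
#' @return A `pepnet_providers` list as in [stub_feature_providers()].
#' @export
file_feature_providers <- function(manifest, sequences,
                                   fallback = stub_feature_providers()) {
  man <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  need <- c("id", "pssm", "ss", "disorder")
  if (!all(need %in% names(man))) {
    stop("feature manifest must have columns id, pssm, ss, disorder", call. = FALSE)
  }
  base <- dirname(normalizePath(manifest))
  resolve <- function(p) {
    if (is.na(p) || p == "-" || p == "") return(NA_character_)
    if (!file.exists(p)) p <- file.path(base, p)
    if (!file.exists(p)) stop("feature file not found: ", p, call. = FALSE)
    p
  }
  id_of <- function(seq) {
    hit <- names(sequences)[match(seq, sequences)]
    if (length(hit) == 0) NA_character_ else hit[1]
  }
  path_for <- function(seq, col) {
    id <- id_of(seq)
    if (is.na(id)) return(NA_character_)
    row <- match(id, man$id)
    if (is.na(row)) return(NA_character_)
    resolve(man[[col]][row])
  }
  pssm <- function(seq) {
    p <- path_for(seq, "pssm")
    if (is.na(p)) return(fallback$pssm(seq))
    m <- as.matrix(utils::read.table(p, header = FALSE))
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    if (ncol(m) != 20) stop("PSSM file must have 20 columns: ", p, call. = FALSE)
    # raw PSI-BLAST-style log-odds are squashed to [0,1]; files already on
    # the probability scale pass through unchanged
    if (any(m < 0) || any(m > 1)) m <- sigmoid(m)
    m
  }
  ss <- function(seq) {
    p <- path_for(seq, "ss")
    if (is.na(p)) return(fallback$ss(seq))
    readLines(p, n = 1L, warn = FALSE)
  }
  disorder <- function(seq) {
    p <- path_for(seq, "disorder")
    if (is.na(p)) return(fallback$disorder(seq))
    m <- as.matrix(utils::read.table(p, header = FALSE, sep = "\t"))
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    if (ncol(m) != 3) stop("disorder file must have 3 columns: ", p, call. = FALSE)
    m
  }
  structure(list(pssm = pssm, ss = ss, disorder = disorder, kind = "file",
                 manifest = manifest),
            class = "pepnet_providers")
}
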