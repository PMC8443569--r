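# Seeded synthetic motif-interaction data: desk-scale datasets with the
# statistical structure the model assumes -- a planted, symbolically
# complementary k-mer rule drives interactions and per-residue binding labels,
# and sequences come in mutated homology families so similarity clustering is
# non-trivial.

#' Default motif library
#'
#' Two complementary (peptide 4-mer, protein 4-mer) pairs. With at least two
#' entries the negative class contains motif-mismatched pairs, so interaction
#' cannot be predicted from motif presence alone -- the pairing has to be
#' learned.
#'
#' @return data.frame with columns `pep`, `pro`.
#' @export
default_motif_library <- function() {
  data.frame(pep = c("WKRF", "HQNC"), pro = c("DEYA", "MGTS"),
             stringsAsFactors = FALSE)
}

#' Synthetic dataset configuration
#'
#' @param n_positives number of positive pairs (one peptide per positive;
#'   default 200).
#' @param ratio negatives per positive (default 5, the benchmark convention).
#' @param pep_len peptide length range (default 5..50).
#' @param pro_len protein length range (default 51..300).
#' @param motifs motif library: data.frame of complementary `pep`/`pro`
#'   k-mers (default [default_motif_library()], k = 4).
#' @param eta residue label-noise rate in [0, 0.5): each binding label is
#'   flipped independently with this probability (default 0, the clean
#'   construction).
#' @param n_families homology families per role; sequences are mutated copies
#'   of a family ancestor (default 5).
#' @param mutation_rate per-position substitution rate within a family
#'   (default 0.05, keeping within-family similarity high).
#' @param n_proteins protein pool size (default `max(20, n_positives / 5)`).
#' @param seed integer seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_positives = 200L, ratio = 5L,
                             pep_len = c(5L, 50L), pro_len = c(51L, 300L),
                             motifs = default_motif_library(),
                             eta = 0, n_families = 5L, mutation_rate = 0.05,
                             n_proteins = NULL, seed = 1L) {
  if (eta < 0 || eta >= 0.5) stop("`eta` must be in [0, 0.5)", call. = FALSE)
  if (mutation_rate < 0 || mutation_rate >= 0.5) {
    stop("`mutation_rate` must be in [0, 0.5)", call. = FALSE)
  }
  k <- unique(nchar(c(motifs$pep, motifs$pro)))
  if (length(k) != 1L) stop("all motifs must share one k-mer length", call. = FALSE)
  if (k > pep_len[1]) {
    stop("motif length ", k, " exceeds the minimum peptide length ", pep_len[1],
         call. = FALSE)
  }
  if (pep_len[2] > 50L || pro_len[1] <= 50L) {
    stop("length ranges must respect the role bounds (peptide <= 50 < protein)",
         call. = FALSE)
  }
  structure(list(n_positives = as.integer(n_positives), ratio = as.integer(ratio),
                 pep_len = as.integer(pep_len), pro_len = as.integer(pro_len),
                 motifs = motifs, k = as.integer(k), eta = eta,
                 n_families = as.integer(n_families),
                 mutation_rate = mutation_rate,
                 n_proteins = as.integer(n_proteins %||%
                                           max(20, ceiling(n_positives / 5))),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

canonical_letters <- function() setdiff(residue_alphabet()$symbols, "X")

random_seq <- function(len) {
  paste(sample(canonical_letters(), len, replace = TRUE), collapse = "")
}

#' Expand ancestor sequences into mutated family copies
#'
#' Each copy differs from its ancestor by i.i.d. substitutions at the given
#' rate (substituted letters are drawn uniformly from the other 19 canonical
#' letters). Family membership is recorded so clustering can be checked
#' against ground truth.
#'
#' @param ancestors named character vector of ancestor sequences.
#' @param copies copies per ancestor.
#' @param mutation_rate per-position substitution probability in [0, 0.5).
#' @param seed integer seed.
#' @return list with `sequences` (named character vector) and `family`
#'   (named character vector mapping copy id to ancestor name).
#' @export
family_expand <- function(ancestors, copies, mutation_rate, seed = 1L) {
  if (mutation_rate < 0 || mutation_rate >= 0.5) {
    stop("`mutation_rate` must be in [0, 0.5)", call. = FALSE)
  }
  letters20 <- canonical_letters()
  with_seed(seed, {
    seqs <- character(0)
    fam <- character(0)
    for (a in names(ancestors)) {
      anc <- strsplit(ancestors[[a]], "")[[1]]
      for (cp in seq_len(copies)) {
        s <- anc
        hit <- which(stats::runif(length(s)) < mutation_rate)
        for (pos in hit) {
          s[pos] <- sample(setdiff(letters20, s[pos]), 1)
        }
        id <- paste0(a, "_", cp)
        seqs[id] <- paste(s, collapse = "")
        fam[id] <- a
      }
    }
    list(sequences = seqs, family = fam)
  })
}

# TRUE if any library entry has its peptide k-mer in `pep_seq` AND its protein
# k-mer in `pro_seq`.
has_complementary_motif <- function(pep_seq, pro_seq, motifs) {
  any(vapply(seq_len(nrow(motifs)), function(m) {
    grepl(motifs$pep[m], pep_seq, fixed = TRUE) &&
      grepl(motifs$pro[m], pro_seq, fixed = TRUE)
  }, logical(1)))
}

# draw a background of family `fam` (mutated ancestor), plant the k-mer of
# motif `m` at a random position, and reject backgrounds that accidentally
# contain any other library k-mer for the role
plant_motif <- function(background, kmer, other_kmers) {
  k <- nchar(kmer)
  n <- nchar(background)
  for (attempt in 1:100) {
    start <- sample.int(n - k + 1L, 1L)
    s <- paste0(substr(background, 1, start - 1L), kmer,
                substr(background, start + k, n))
    others_absent <- !any(vapply(other_kmers, grepl, logical(1), x = s,
                                 fixed = TRUE))
    if (others_absent) return(list(seq = s, start = start))
    # re-randomize the offending background positions by reshuffling letters
    background <- random_seq(n)
  }
  stop("could not plant motif without collisions", call. = FALSE)
}

#' Generate a synthetic motif-interaction dataset
#'
#' Builds peptide and protein pools as mutated homology families, assigns
#' every entity one motif index from the library and plants the corresponding
#' k-mer at a recorded position. Positive pairs match a peptide with a protein
#' of the same motif index; their binding vector is 1 exactly at the planted
#' peptide motif positions, then each label is flipped independently with
#' probability `eta`. Negatives are sampled uniformly without replacement
#' from motif-mismatched peptide x protein combinations (so no negative
#' contains a complementary motif pair) at `ratio` per positive. Fully
#' seeded and deterministic.
#'
#' @param cfg a [synthetic_config()].
#' @return list of class `pepnet_sim` with `table` (a [pair_table()]),
#'   `truth` (per-entity motif index, motif start positions, family labels,
#'   and the noiseless binding vectors), and `cfg`.
#' @export
simulate_interactions <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  motifs <- cfg$motifs
  n_motif <- nrow(motifs)
  with_seed(cfg$seed, {
    make_pool <- function(prefix, n, len_range, role_kmers) {
      n_fam <- cfg$n_families
      anc_len <- pmax(len_range[1],
                      sample(len_range[1]:len_range[2], n_fam, replace = TRUE))
      ancestors <- stats::setNames(
        vapply(anc_len, random_seq, character(1)),
        paste0(prefix, "fam", seq_len(n_fam)))
      copies <- ceiling(n / n_fam)
      fe_seed <- sample.int(.Machine$integer.max, 1L)
      ex <- family_expand(ancestors, copies, cfg$mutation_rate, seed = fe_seed)
      keep <- names(ex$sequences)[seq_len(n)]
      seqs <- ex$sequences[keep]
      fam <- ex$family[keep]
      motif_of <- stats::setNames(
        rep_len(sample.int(n_motif, n, replace = TRUE), n), keep)
      start_of <- stats::setNames(integer(n), keep)
      for (id in keep) {
        kmer <- role_kmers[motif_of[[id]]]
        pl <- plant_motif(seqs[[id]], kmer, setdiff(role_kmers, kmer))
        seqs[id] <- pl$seq
        start_of[id] <- pl$start
      }
      list(seqs = seqs, family = fam, motif = motif_of, start = start_of)
    }

    pep <- make_pool("pep_", cfg$n_positives, cfg$pep_len, motifs$pep)
    pro <- make_pool("pro_", cfg$n_proteins, cfg$pro_len, motifs$pro)

    # positives: each peptide paired with a random protein of matching motif
    pos <- data.frame(peptide_id = character(0), protein_id = character(0))
    truth_bind <- list()
    for (id in names(pep$seqs)) {
      match_pros <- names(pro$seqs)[pro$motif == pep$motif[[id]]]
      if (length(match_pros) == 0) {
        stop("no protein carries motif index ", pep$motif[[id]],
             "; increase `n_proteins`", call. = FALSE)
      }
      pid <- match_pros[sample.int(length(match_pros), 1L)]
      pos <- rbind(pos, data.frame(peptide_id = id, protein_id = pid,
                                   stringsAsFactors = FALSE))
      bv <- integer(nchar(pep$seqs[[id]]))
      bv[pep$start[[id]]:(pep$start[[id]] + cfg$k - 1L)] <- 1L
      truth_bind[[id]] <- bv
    }
    pos <- pos[!duplicated(paste(pos$peptide_id, pos$protein_id)), , drop = FALSE]
    noisy_bind <- vapply(pos$peptide_id, function(id) {
      bv <- truth_bind[[id]]
      if (cfg$eta > 0) {
        flip <- stats::runif(length(bv)) < cfg$eta
        bv[flip] <- 1L - bv[flip]
      }
      format_bind(bv)
    }, character(1))
    pos$label <- 1L
    pos$bind <- noisy_bind

    # negatives: uniform over motif-mismatched combinations
    grid <- expand.grid(peptide_id = names(pep$seqs),
                        protein_id = names(pro$seqs),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    compatible <- pep$motif[grid$peptide_id] == pro$motif[grid$protein_id]
    pos_key <- paste(pos$peptide_id, pos$protein_id, sep = "\r")
    candidate <- which(!compatible &
                         !(paste(grid$peptide_id, grid$protein_id, sep = "\r")
                           %in% pos_key))
    n_need <- cfg$ratio * nrow(pos)
    if (length(candidate) < n_need) {
      stop("not enough motif-mismatched combinations for the requested ratio",
           call. = FALSE)
    }
    neg_idx <- candidate[sample.int(length(candidate), n_need)]
    neg <- data.frame(peptide_id = grid$peptide_id[neg_idx],
                      protein_id = grid$protein_id[neg_idx],
                      label = 0L, bind = NA_character_,
                      stringsAsFactors = FALSE)

    tab <- pair_table(rbind(pos[, c("peptide_id", "protein_id", "label", "bind")],
                            neg),
                      peptides = pep$seqs, proteins = pro$seqs)
    structure(list(
      table = tab,
      truth = list(
        pep_motif = pep$motif, pro_motif = pro$motif,
        pep_start = pep$start, pro_start = pro$start,
        pep_family = pep$family, pro_family = pro$family,
        bind = truth_bind,
        motifs = motifs
      ),
      cfg = cfg
    ), class = "pepnet_sim")
  })
}

#' @export
print.pepnet_sim <- function(x, ...) {
  cat(sprintf("<pepnet_sim> %d positives, ratio 1:%d, %d peptides x %d proteins, eta = %g\n",
              x$cfg$n_positives, x$cfg$ratio, length(x$table$peptides),
              length(x$table$proteins), x$cfg$eta))
  invisible(x)
}
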