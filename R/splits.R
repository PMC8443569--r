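# Homology-aware cross-validation machinery: normalized Smith-Waterman
# similarity, single-linkage clustering at a threshold, fold construction for
# the random / novel-protein / novel-peptide / novel-pair settings, negative
# sampling at a fixed class ratio, and a leakage audit.

sw_score <- function(a, b, submat, gap_open, gap_extend) {
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = submat, gapOpening = gap_open,
    gapExtension = gap_extend, scoreOnly = TRUE))
}

get_submat <- function(name = "BLOSUM62") {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Normalized Smith-Waterman similarity
#'
#' Local-alignment score normalized by the geometric mean of the two
#' self-alignment scores: `SW(a, b) / sqrt(SW(a, a) * SW(b, b))`, using
#' BLOSUM62 with gap open 11 / extend 1 by default. Symmetric, 1 for
#' identical sequences, and in [0, 1] for standard scoring schemes.
#'
#' @param a,b non-empty residue strings.
#' @param submat substitution matrix (default BLOSUM62).
#' @param gap_open,gap_extend gap penalties (defaults 11 and 1).
#' @return similarity in [0, 1].
#' @export
normalized_sw <- function(a, b, submat = get_submat("BLOSUM62"),
                          gap_open = 11, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty", call. = FALSE)
  s_ab <- sw_score(a, b, submat, gap_open, gap_extend)
  s_aa <- sw_score(a, a, submat, gap_open, gap_extend)
  s_bb <- sw_score(b, b, submat, gap_open, gap_extend)
  max(0, s_ab) / sqrt(s_aa * s_bb)
}

#' Pairwise normalized Smith-Waterman similarity matrix
#'
#' @param seqs named character vector of sequences.
#' @inheritParams normalized_sw
#' @return symmetric matrix with unit diagonal, dimnames from `seqs`.
#' @export
sw_similarity_matrix <- function(seqs, submat = get_submat("BLOSUM62"),
                                 gap_open = 11, gap_extend = 1) {
  n <- length(seqs)
  ids <- names(seqs) %||% as.character(seq_len(n))
  self <- vapply(seqs, function(s) sw_score(s, s, submat, gap_open, gap_extend),
                 numeric(1))
  sim <- diag(1, n)
  if (n > 1) {
    set <- Biostrings::AAStringSet(seqs)
    for (j in 2:n) {
      sc <- as.numeric(Biostrings::pairwiseAlignment(
        set[seq_len(j - 1)], Biostrings::AAString(seqs[[j]]), type = "local",
        substitutionMatrix = submat, gapOpening = gap_open,
        gapExtension = gap_extend, scoreOnly = TRUE))
      sim[seq_len(j - 1), j] <- pmax(0, sc) / sqrt(self[seq_len(j - 1)] * self[j])
      sim[j, seq_len(j - 1)] <- sim[seq_len(j - 1), j]
    }
  }
  dimnames(sim) <- list(ids, ids)
  sim
}

#' Single-linkage clustering of sequences at a similarity threshold
#'
#' Connected components of the graph whose edges join sequence pairs with
#' normalized Smith-Waterman similarity at or above `t`. Cluster ids are the
#' lexicographically smallest member id, making the assignment deterministic.
#'
#' @param seqs named character vector of sequences.
#' @param t similarity threshold in (0, 1].
#' @param sim optional pre-computed similarity matrix from
#'   [sw_similarity_matrix()] (rows/cols named like `seqs`).
#' @return named character vector: sequence id -> cluster id.
#' @export
cluster_entities <- function(seqs, t, sim = NULL) {
  if (t <= 0 || t > 1) stop("`t` must be in (0, 1]", call. = FALSE)
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  if (is.null(sim)) sim <- sw_similarity_matrix(seqs)
  sim <- sim[ids, ids, drop = FALSE]
  adj <- sim >= t
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  cluster_of <- vapply(split(ids, comp), function(members) min(members),
                       character(1))
  stats::setNames(cluster_of[as.character(comp)], ids)
}

#' Construct cross-validation folds under a splitting regime
#'
#' Builds train/test partitions of the pair set under one of four settings:
#' \describe{
#'   \item{random}{seeded k-fold partition of the pairs, no homology
#'     constraint.}
#'   \item{novel_protein}{protein clusters (single linkage at threshold `t`)
#'     are assigned to k groups; a fold tests on the pairs of one group and
#'     trains on the rest, so no protein cluster straddles the boundary.}
#'   \item{novel_peptide}{same with peptide clusters.}
#'   \item{novel_pair}{peptide clusters and protein clusters are each split
#'     into 3 groups; the 3 x 3 grid yields 9 folds where the test block
#'     shares neither a peptide cluster nor a protein cluster with its train
#'     block (some pairs are unused per fold by construction).}
#' }
#' Cluster groups are balanced greedily by pair count (largest cluster first
#' into the lightest group), which is deterministic; the seed drives the
#' random setting and tie-breaking shuffles.
#'
#' @param table a [pair_table()] with sequences (not needed for `random`).
#' @param setting one of `"random"`, `"novel_protein"`, `"novel_peptide"`,
#'   `"novel_pair"`.
#' @param t similarity threshold for clustering (default 0.4).
#' @param k number of folds (default 5; the novel_pair grid is fixed at
#'   3 x 3 = 9 folds).
#' @param seed integer seed.
#' @param sim_pep,sim_pro optional pre-computed similarity matrices.
#' @return object of class `fold_plan`: `setting`, `threshold`, `folds`
#'   (list of `list(train, test)` index vectors into `table$pairs`),
#'   `pep_clusters`, `pro_clusters`, `k`, `seed`.
#' @export
make_folds <- function(table, setting = c("random", "novel_protein",
                                          "novel_peptide", "novel_pair"),
                       t = 0.4, k = 5L, seed = 1L,
                       sim_pep = NULL, sim_pro = NULL) {
  setting <- match.arg(setting)
  stopifnot(inherits(table, "pair_table"))
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be at least 2", call. = FALSE)
  pairs <- table$pairs
  n <- nrow(pairs)

  pep_clusters <- NULL
  pro_clusters <- NULL
  if (setting %in% c("novel_peptide", "novel_pair")) {
    pep_clusters <- cluster_entities(table$peptides, t, sim_pep)
  }
  if (setting %in% c("novel_protein", "novel_pair")) {
    pro_clusters <- cluster_entities(table$proteins, t, sim_pro)
  }

  # assign clusters to `groups` groups, balancing total pair count
  assign_groups <- function(clusters, entity_ids, groups) {
    counts <- table(factor(clusters[entity_ids], levels = unique(clusters)))
    counts <- counts[counts > 0]
    if (length(counts) < groups) {
      stop("only ", length(counts), " clusters at threshold; cannot fill ",
           groups, " groups", call. = FALSE)
    }
    ord <- order(-as.numeric(counts), names(counts))
    load <- numeric(groups)
    g_of <- stats::setNames(integer(length(counts)), names(counts)[ord])
    for (cl in names(counts)[ord]) {
      g <- which.min(load)
      g_of[cl] <- g
      load[g] <- load[g] + counts[[cl]]
    }
    g_of
  }

  folds <- switch(setting,
    random = with_seed(seed, {
      grp <- sample(rep_len(seq_len(k), n))
      lapply(seq_len(k), function(g) {
        list(train = which(grp != g), test = which(grp == g))
      })
    }),
    novel_protein = {
      g_of <- assign_groups(pro_clusters, pairs$protein_id, k)
      pg <- unname(g_of[pro_clusters[pairs$protein_id]])
      lapply(seq_len(k), function(g) {
        list(train = which(pg != g), test = which(pg == g))
      })
    },
    novel_peptide = {
      g_of <- assign_groups(pep_clusters, pairs$peptide_id, k)
      pg <- unname(g_of[pep_clusters[pairs$peptide_id]])
      lapply(seq_len(k), function(g) {
        list(train = which(pg != g), test = which(pg == g))
      })
    },
    novel_pair = {
      g_pep <- assign_groups(pep_clusters, pairs$peptide_id, 3L)
      g_pro <- assign_groups(pro_clusters, pairs$protein_id, 3L)
      pgp <- unname(g_pep[pep_clusters[pairs$peptide_id]])
      pgr <- unname(g_pro[pro_clusters[pairs$protein_id]])
      out <- list()
      for (i in 1:3) for (j in 1:3) {
        out[[length(out) + 1L]] <- list(
          train = which(pgp != i & pgr != j),
          test = which(pgp == i & pgr == j)
        )
      }
      out
    }
  )
  empty <- vapply(folds, function(f) length(f$test) == 0 || length(f$train) == 0,
                  logical(1))
  if (any(empty)) {
    warning(sum(empty), " fold(s) have an empty train or test block", call. = FALSE)
  }
  structure(list(setting = setting, threshold = if (setting == "random") NA_real_ else t,
                 folds = folds, pep_clusters = pep_clusters,
                 pro_clusters = pro_clusters, k = if (setting == "novel_pair") 9L else k,
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  sizes <- vapply(x$folds, function(f) length(f$test), integer(1))
  cat(sprintf("<fold_plan> setting %s, threshold %s, %d folds (test sizes: %s)\n",
              x$setting, format(x$threshold), length(x$folds),
              paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Audit a fold plan for homology leakage
#'
#' Verifies the disjointness contract of the plan's setting: in novel_protein
#' folds no protein cluster may appear on both sides of the split, likewise
#' for peptides in novel_peptide, and for both entity types in novel_pair.
#' The random setting has no constraint and always passes.
#'
#' @param plan a `fold_plan`.
#' @param table the [pair_table()] the plan was built from.
#' @return list with `ok` (logical) and `violations` (data.frame with columns
#'   `fold`, `entity_id`).
#' @export
leakage_check <- function(plan, table) {
  stopifnot(inherits(plan, "fold_plan"), inherits(table, "pair_table"))
  pairs <- table$pairs
  violations <- data.frame(fold = integer(), entity_id = character())
  check_entity <- function(clusters, ids_col) {
    for (f in seq_along(plan$folds)) {
      tr <- unique(clusters[pairs[[ids_col]][plan$folds[[f]]$train]])
      te_ids <- unique(pairs[[ids_col]][plan$folds[[f]]$test])
      bad <- te_ids[clusters[te_ids] %in% tr]
      if (length(bad)) {
        violations <<- rbind(violations,
                             data.frame(fold = f, entity_id = bad))
      }
    }
  }
  if (plan$setting %in% c("novel_protein", "novel_pair")) {
    check_entity(plan$pro_clusters, "protein_id")
  }
  if (plan$setting %in% c("novel_peptide", "novel_pair")) {
    check_entity(plan$pep_clusters, "peptide_id")
  }
  list(ok = nrow(violations) == 0, violations = violations)
}

#' Sample negative pairs at a fixed class ratio
#'
#' Draws `ratio` negatives per positive uniformly without replacement from the
#' peptide x protein combinations that are not known positives, excluding
#' duplicates. The returned table has `(1 + ratio) * n_positive` rows.
#'
#' @param table a [pair_table()] whose rows are the known positives (label 1).
#' @param ratio non-negative integer negatives per positive (default 5).
#' @param seed integer seed.
#' @param peptide_ids,protein_ids candidate id universes; default to the ids
#'   present in the table (or its sequence maps when available).
#' @return a [pair_table()] with the positives followed by the sampled
#'   negatives (label 0, no binding vector).
#' @export
sample_negatives <- function(table, ratio = 5L, seed = 1L,
                             peptide_ids = NULL, protein_ids = NULL) {
  stopifnot(inherits(table, "pair_table"))
  ratio <- as.integer(ratio)
  if (ratio < 0) stop("`ratio` must be non-negative", call. = FALSE)
  if (ratio == 0L) return(table)
  pos <- table$pairs[table$pairs$label == 1L, , drop = FALSE]
  peptide_ids <- peptide_ids %||% names(table$peptides) %||% unique(pos$peptide_id)
  protein_ids <- protein_ids %||% names(table$proteins) %||% unique(pos$protein_id)
  np <- length(peptide_ids)
  nq <- length(protein_ids)
  n_pos <- nrow(pos)
  n_need <- ratio * n_pos
  total <- as.double(np) * as.double(nq)
  if (total - n_pos < n_need) {
    stop("not enough non-positive combinations: ", format(total - n_pos),
         " available, ", n_need, " required", call. = FALSE)
  }
  if (total >= 2^31) {
    stop("combination space too large to index; supply smaller id universes",
         call. = FALSE)
  }
  pos_idx <- (match(pos$protein_id, protein_ids) - 1L) * np +
    match(pos$peptide_id, peptide_ids)
  chosen <- with_seed(seed, {
    acc <- integer(0)
    while (length(acc) < n_need) {
      draw <- sample.int(as.integer(total), min(as.integer(total),
                                                ceiling((n_need - length(acc)) * 1.3) + 16L))
      draw <- setdiff(draw, pos_idx)
      acc <- unique(c(acc, draw))
    }
    acc[seq_len(n_need)]
  })
  neg <- data.frame(
    peptide_id = peptide_ids[((chosen - 1L) %% np) + 1L],
    protein_id = protein_ids[((chosen - 1L) %/% np) + 1L],
    label = 0L,
    bind = NA_character_,
    stringsAsFactors = FALSE
  )
  pair_table(rbind(pos[, c("peptide_id", "protein_id", "label", "bind")], neg),
             table$peptides, table$proteins)
}

#' Exhaustively pair candidate peptides with candidate proteins
#'
#' Builds the full cross-product pair list used for screening-style
#' independent tests (every candidate peptide against every candidate
#' protein), optionally excluding known pairs.
#'
#' @param peptide_ids,protein_ids candidate id vectors.
#' @param exclude optional data.frame with `peptide_id`, `protein_id` columns
#'   to drop from the cross-product.
#' @return data.frame with columns `peptide_id`, `protein_id`.
#' @export
candidate_pairs <- function(peptide_ids, protein_ids, exclude = NULL) {
  out <- expand.grid(peptide_id = as.character(peptide_ids),
                     protein_id = as.character(protein_ids),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (!is.null(exclude) && nrow(exclude) > 0) {
    key <- paste(out$peptide_id, out$protein_id, sep = "\r")
    drop <- paste(exclude$peptide_id, exclude$protein_id, sep = "\r")
    out <- out[!key %in% drop, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
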