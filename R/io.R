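# Text IO: the pair-table TSV dialect, FASTA via Biostrings, fold-plan JSON,
# and the scored prediction TSV written by the command-line interface.

#' Read / write a pair table as TSV
#'
#' The pair-table dialect has four tab-separated columns: `peptide_id`,
#' `protein_id`, `label` (0/1) and `binding_vector` (comma-separated 0/1 over
#' the peptide's residues, or `-` when absent). `read_pairs` validates every
#' row and reports the first malformed line by number; binding-vector lengths
#' are checked against the peptide sequences when maps are supplied.
#'
#' @param path TSV file path.
#' @param peptides,proteins optional named sequence vectors attached to the
#'   returned table (and used for validation).
#' @return `read_pairs`: a [pair_table()]. `write_pairs`: the path, invisibly.
#' @export
read_pairs <- function(path, peptides = NULL, proteins = NULL) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("peptide_id", "protein_id", "label", "binding_vector")
  if (!all(need %in% names(raw))) {
    stop("pair TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lab <- suppressWarnings(as.integer(raw$label))
  bad <- which(is.na(lab) | !(lab %in% c(0L, 1L)))
  if (length(bad)) {
    stop("malformed label at line ", bad[1] + 1L, " of ", path, call. = FALSE)
  }
  for (i in seq_len(nrow(raw))) {
    bv <- raw$binding_vector[i]
    if (!is.na(bv) && bv != "-" && bv != "") {
      ok <- grepl("^[01](,[01])*$", bv)
      if (!ok) stop("malformed binding vector at line ", i + 1L, " of ", path,
                    call. = FALSE)
    }
  }
  pair_table(data.frame(peptide_id = raw$peptide_id,
                        protein_id = raw$protein_id,
                        label = lab,
                        bind = raw$binding_vector,
                        stringsAsFactors = FALSE),
             peptides = peptides, proteins = proteins)
}

#' @rdname read_pairs
#' @param table a [pair_table()] to write.
#' @export
write_pairs <- function(table, path) {
  stopifnot(inherits(table, "pair_table"))
  out <- data.frame(peptide_id = table$pairs$peptide_id,
                    protein_id = table$pairs$protein_id,
                    label = table$pairs$label,
                    binding_vector = ifelse(is.na(table$pairs$bind), "-",
                                            table$pairs$bind),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sequences as FASTA
#'
#' @param path FASTA file.
#' @param role optional role used to validate lengths (`"peptide"` <= 50 <
#'   `"protein"`).
#' @return `read_fasta`: named character vector of uppercased sequences.
#' @export
read_fasta <- function(path, role = NULL) {
  set <- Biostrings::readAAStringSet(path)
  seqs <- stats::setNames(toupper(as.character(set)),
                          sub("\\s.*$", "", names(set)))
  if (!is.null(role)) {
    for (id in names(seqs)) sequence_record(id, role, seqs[[id]])
  }
  seqs
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences to write.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Serialize / restore a fold plan as JSON
#'
#' @param plan a `fold_plan` from [make_folds()].
#' @param path JSON file path.
#' @return `read_fold_plan` returns the `fold_plan`.
#' @export
write_fold_plan <- function(plan, path) {
  stopifnot(inherits(plan, "fold_plan"))
  payload <- list(
    setting = plan$setting,
    threshold = plan$threshold,
    k = plan$k,
    seed = plan$seed,
    folds = lapply(plan$folds, function(f) list(train = f$train, test = f$test)),
    pep_clusters = as.list(plan$pep_clusters),
    pro_clusters = as.list(plan$pro_clusters)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  folds <- lapply(seq_len(nrow_or_len(p$folds)), function(i) {
    f <- if (is.data.frame(p$folds)) list(train = p$folds$train[[i]],
                                          test = p$folds$test[[i]])
         else p$folds[[i]]
    list(train = as.integer(f$train), test = as.integer(f$test))
  })
  structure(list(setting = p$setting,
                 threshold = if (is.null(p$threshold)) NA_real_ else p$threshold,
                 folds = folds,
                 pep_clusters = unlist_or_null(p$pep_clusters),
                 pro_clusters = unlist_or_null(p$pro_clusters),
                 k = as.integer(p$k), seed = as.integer(p$seed)),
            class = "fold_plan")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

unlist_or_null <- function(x) {
  if (is.null(x) || length(x) == 0) return(NULL)
  unlist(x)
}

#' Read / write a run configuration (YAML or JSON)
#'
#' Run configurations are plain nested lists (command options, architecture
#' and training fields); both formats round-trip losslessly for scalar and
#' vector fields.
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return `read_run_config`: a named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname read_run_config
#' @param config named list to write.
#' @export
write_run_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(config, path)
  else jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

#' Write scored predictions as TSV
#'
#' One row per pair: the interaction probability, the binary call at 0.5, and
#' the per-residue scores over the peptide's true length as a comma-separated
#' list (positions are 1-based along the peptide). Failed pairs keep their
#' row with `NA` score and the error in `note`.
#'
#' @param predictions output of [predict.pepnet()].
#' @param path TSV file path.
#' @return the path, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  out <- data.frame(
    peptide_id = predictions$peptide_id,
    protein_id = predictions$protein_id,
    score = predictions$prob,
    call = predictions$pred,
    residue_scores = vapply(predictions$residue_scores, function(v) {
      if (is.null(v)) "-" else paste(formatC(v, digits = 6, format = "g"),
                                     collapse = ",")
    }, character(1)),
    note = ifelse(is.na(predictions$note), "-", predictions$note),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# residue_scores: comma-separated, 1-based peptide positions", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
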