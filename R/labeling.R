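#' Per-ADR class labels from a SIDER-like annotation table
#'
#' For a given ADR: a drug with a `side_effect` row is class 1; an
#' `indication` row overrides to class 0 (preventing false-positive labels);
#' an annotated drug with neither row is class 0 ("not known to induce");
#' a drug absent from the table is held out and never used in training.
#'
#' @param drug_ids character vector of drugs to label.
#' @param adr one of nausea, vomiting, diarrhoea, constipation.
#' @param table annotation data.frame (`drug_id`, `adr`, `relation`).
#' @return character vector: "0", "1" or "held_out" per drug.
#' @export
assign_class <- function(drug_ids, adr, table) {
  if (!adr %in% ADRS) stop(sprintf("unknown ADR '%s'", adr))
  annotated <- unique(table$drug_id)
  se <- unique(table$drug_id[table$adr == adr &
                               table$relation == "side_effect"])
  ind <- unique(table$drug_id[table$adr == adr &
                                table$relation == "indication"])
  out <- rep("held_out", length(drug_ids))
  out[drug_ids %in% annotated] <- "0"
  out[drug_ids %in% se] <- "1"
  out[drug_ids %in% ind] <- "0"          # indication overrides side_effect
  setNames(out, drug_ids)
}

#' Build balanced chunks for one ADR
#'
#' Each balanced chunk holds every dataset of the minority class plus a
#' fresh random sample of equal size from the majority class; majority
#' samples are disjoint across chunks. Held-out drugs are excluded. For a
#' single chunk on a nearly balanced problem (majority at most 25% larger
#' than the minority) all datasets are retained unsampled.
#'
#' @param metadata data.frame with `dataset_id` and `drug`.
#' @param adr the target ADR.
#' @param table annotation table.
#' @param n_chunks requested number of chunks; reduced with a warning when
#'   the majority class cannot supply disjoint samples.
#' @param seed integer seed.
#' @return list of `sw_chunk` objects: `adr`, `chunk_index`, `dataset_ids`,
#'   `labels` (named 0/1 integer), `majority_ids_used`.
#' @export
make_balanced_chunks <- function(metadata, adr, table, n_chunks = 2,
                                 seed = 1L) {
  lab <- assign_class(metadata$drug, adr, table)
  keep <- lab != "held_out"
  ids <- metadata$dataset_id[keep]
  y <- as.integer(lab[keep])
  if (!length(ids) || length(unique(y)) < 2) {
    stop(sprintf("one class is empty for ADR '%s'", adr))
  }
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  minority <- if (n1 <= n0) 1L else 0L
  min_ids <- ids[y == minority]
  maj_ids <- ids[y != minority]
  if (n_chunks == 1 && length(maj_ids) <= 1.25 * length(min_ids)) {
    # nearly balanced single-chunk case: retain everything
    labels <- setNames(y, ids)
    return(list(structure(list(adr = adr, chunk_index = 0L,
                               dataset_ids = ids, labels = labels,
                               majority_ids_used = maj_ids),
                          class = "sw_chunk")))
  }
  max_chunks <- floor(length(maj_ids) / length(min_ids))
  if (n_chunks > max_chunks) {
    warning(sprintf("reducing n_chunks from %d to %d for ADR '%s'",
                    n_chunks, max_chunks, adr))
    n_chunks <- max_chunks
  }
  with_seed(derive_seed(seed, "chunks", adr), {
    pool <- sample(maj_ids)
    lapply(seq_len(n_chunks), function(k) {
      take <- pool[((k - 1) * length(min_ids) + 1):(k * length(min_ids))]
      cids <- c(min_ids, take)
      labels <- setNames(ifelse(cids %in% min_ids, minority, 1L - minority),
                         cids)
      structure(list(adr = adr, chunk_index = k - 1L, dataset_ids = cids,
                     labels = labels, majority_ids_used = take),
                class = "sw_chunk")
    })
  })
}

#' Stratified 8:2 train/validation split at the dataset level
#'
#' Random sampling within each class so that class proportions in the
#' training set stay within one dataset of the chunk proportions; the split
#' ignores tissue and concentration (those enter the models as embeddings).
#'
#' @param chunk an `sw_chunk`.
#' @param ratio training fraction (default 0.8).
#' @param seed integer seed.
#' @return list with `train_ids` and `val_ids` (disjoint, exhaustive).
#' @export
split_train_val <- function(chunk, ratio = 0.8, seed = 1L) {
  ids <- chunk$dataset_ids
  if (length(ids) < 5) stop("chunk smaller than 5 datasets")
  y <- chunk$labels[ids]
  with_seed(derive_seed(seed, "split", chunk$adr, chunk$chunk_index), {
    train <- character(0)
    for (cl in sort(unique(y))) {
      cls <- ids[y == cl]
      train <- c(train, sample(cls, round(ratio * length(cls))))
    }
    list(train_ids = sort(train), val_ids = sort(setdiff(ids, train)))
  })
}

#' Shuffle training labels (negative-correlation control)
#'
#' Uniform random permutation of the training labels only; the label
#' multiset is conserved and validation/test labels are untouched.
#'
#' @param labels named integer vector of training labels.
#' @param seed integer seed.
#' @return labels permuted over the same names.
#' @export
shuffle_labels <- function(labels, seed = 1L) {
  with_seed(derive_seed(seed, "shuffle"), {
    setNames(sample(as.integer(labels)), names(labels))
  })
}
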