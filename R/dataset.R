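#' Labeled sequence datasets
#'
#' A labeled dataset is a tibble with columns `id` (unique), `sequence`,
#' `label` (numeric fitness for regression, 0/1 for classification) and `set`
#' (one of `"train"`, `"valid"`, `"test"`, `"unassigned"`), carrying
#' `alphabet` (`"amino_acid"` or `"nucleotide"`) and `task` (`"regression"`
#' or `"classification"`) as attributes.
#'
#' @param sequence Character vector of sequences.
#' @param label Numeric labels (0/1 for classification).
#' @param id Optional record ids; defaults to `"s1"`, `"s2"`, ...
#' @param set Optional split tags; default `"unassigned"`.
#' @param alphabet `"amino_acid"` or `"nucleotide"`.
#' @param task `"regression"` or `"classification"`.
#' @return A tibble of class `nta_dataset`.
#' @export
labeled_dataset <- function(sequence, label, id = NULL, set = NULL,
                            alphabet = c("amino_acid", "nucleotide"),
                            task = c("regression", "classification")) {
  alphabet <- match.arg(alphabet)
  task <- match.arg(task)
  n <- length(sequence)
  if (is.null(id)) id <- paste0("s", seq_len(n))
  if (is.null(set)) set <- rep("unassigned", n)
  df <- tibble::tibble(
    id = as.character(id),
    sequence = toupper(as.character(sequence)),
    label = as.numeric(label),
    set = as.character(set)
  )
  as_labeled_dataset(df, alphabet = alphabet, task = task)
}

#' @rdname labeled_dataset
#' @param df Data frame with columns `id`, `sequence`, `label`, `set`.
#' @export
as_labeled_dataset <- function(df, alphabet, task) {
  df <- tibble::as_tibble(df)
  required <- c("id", "sequence", "label", "set")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort_ntaug(sprintf("Dataset is missing column(s): %s.",
                        paste(missing, collapse = ", ")), "parse_error")
  }
  if (anyDuplicated(df$id)) {
    abort_ntaug("Dataset ids must be unique.", "parse_error")
  }
  if (anyNA(df$label)) {
    abort_ntaug("Dataset labels must be non-missing numbers.", "parse_error")
  }
  if (task == "classification" && !all(df$label %in% c(0, 1))) {
    abort_ntaug("Classification labels must all be 0 or 1.", "parse_error")
  }
  pattern <- if (alphabet == "amino_acid") {
    paste0("^[", paste(AA_LETTERS, collapse = ""), "]+$")
  } else {
    "^[ACGT]+$"
  }
  bad <- which(!grepl(pattern, df$sequence))
  if (length(bad)) {
    abort_ntaug(
      sprintf("Sequence at row %d violates the %s alphabet.", bad[1], alphabet),
      "parse_error"
    )
  }
  if (!all(df$set %in% c("train", "valid", "test", "unassigned"))) {
    abort_ntaug("Split tags must be train/valid/test/unassigned.", "parse_error")
  }
  attr(df, "alphabet") <- alphabet
  attr(df, "task") <- task
  class(df) <- unique(c("nta_dataset", class(df)))
  df
}

#' @rdname labeled_dataset
#' @param dataset A dataset.
#' @return `dataset_meta()` returns `list(alphabet =, task =)`, inferring
#'   from the data when the attributes have been stripped by subsetting.
#' @export
dataset_meta <- function(dataset) {
  alphabet <- attr(dataset, "alphabet")
  task <- attr(dataset, "task")
  if (is.null(alphabet)) {
    alphabet <- if (all(grepl("^[ACGT]+$", dataset$sequence))) "nucleotide" else "amino_acid"
  }
  if (is.null(task)) {
    task <- if (all(dataset$label %in% c(0, 1))) "classification" else "regression"
  }
  list(alphabet = alphabet, task = task)
}

#' Read and write labeled datasets
#'
#' The canonical on-disk format is a CSV with header columns
#' `sequence,label[,set][,id]`. Alternatively, `format = "fasta+csv"` reads
#' sequences from a FASTA file whose record ids resolve against a sidecar
#' label CSV with columns `id,label[,set]`.
#'
#' @param path CSV path (or FASTA path for `"fasta+csv"`).
#' @param format `"csv"` or `"fasta+csv"`.
#' @param labels_path Sidecar CSV path for `"fasta+csv"`.
#' @param alphabet,task Declared alphabet and task (validated on read).
#' @return A labeled dataset; `write_dataset()` returns `path` invisibly.
#' @export
read_dataset <- function(path, format = c("csv", "fasta+csv"),
                         labels_path = NULL,
                         alphabet = c("amino_acid", "nucleotide"),
                         task = c("regression", "classification")) {
  format <- match.arg(format)
  alphabet <- match.arg(alphabet)
  task <- match.arg(task)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("sequence", "label") %in% names(df))) {
      abort_ntaug(sprintf("'%s' must have header columns sequence,label.", path),
                  "parse_error")
    }
    lab <- suppressWarnings(as.numeric(df$label))
    if (anyNA(lab)) {
      abort_ntaug(
        sprintf("Non-numeric label at line %d of '%s'.",
                which(is.na(lab))[1] + 1L, path),
        "parse_error"
      )
    }
    labeled_dataset(
      sequence = df$sequence, label = lab,
      id = if ("id" %in% names(df)) df$id else NULL,
      set = if ("set" %in% names(df)) df$set else NULL,
      alphabet = alphabet, task = task
    )
  } else {
    if (is.null(labels_path)) {
      abort_ntaug("format 'fasta+csv' needs `labels_path`.", "parse_error")
    }
    seqs <- if (alphabet == "amino_acid") {
      Biostrings::readAAStringSet(path)
    } else {
      Biostrings::readDNAStringSet(path)
    }
    lab_df <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
    if (!all(c("id", "label") %in% names(lab_df))) {
      abort_ntaug("Label CSV must have columns id,label.", "parse_error")
    }
    ids <- sub("\\s.*$", "", names(seqs))
    m <- match(ids, lab_df$id)
    if (anyNA(m)) {
      abort_ntaug(
        sprintf("FASTA id '%s' has no label in '%s'.", ids[which(is.na(m))[1]],
                labels_path),
        "parse_error"
      )
    }
    labeled_dataset(
      sequence = as.character(seqs), label = as.numeric(lab_df$label[m]),
      id = ids,
      set = if ("set" %in% names(lab_df)) lab_df$set[m] else NULL,
      alphabet = alphabet, task = task
    )
  }
}

#' @rdname read_dataset
#' @param dataset A labeled dataset.
#' @export
write_dataset <- function(dataset, path) {
  cols <- intersect(c("id", "sequence", "label", "set", "parent_id", "aug_index"),
                    names(dataset))
  utils::write.csv(as.data.frame(dataset)[, cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
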