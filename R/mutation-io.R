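#' Columns of the annotated mutation table
#'
#' The native tab-separated dialect used throughout the package. One row per
#' observed mutation:
#' \describe{
#'   \item{population}{Population label, e.g. `"Ara+3"`.}
#'   \item{position}{1-based chromosome position.}
#'   \item{mclass}{Mutation class: `point`, `indel` or `sv` (structural
#'     variant, i.e. a novel junction, mostly IS-element transpositions).}
#'   \item{base_from, base_to}{Reference and derived base for point
#'     mutations; empty otherwise.}
#'   \item{annotation}{Functional annotation: `synonymous`, `missense`,
#'     `nonsense`, `noncoding`, `indel` or `sv`.}
#'   \item{gene}{Gene name, or `"intergenic"`.}
#'   \item{appearance_time}{Generations at which the mutation is first
#'     reliably observed in the time series.}
#'   \item{fate}{`fixed`, `extinct` or `polymorphic` (still segregating at
#'     the end of the series).}
#'   \item{is_associated}{For `sv` records, whether the junction is
#'     IS-element associated; `NA` otherwise.}
#' }
#'
#' @return Character vector of column names.
#' @export
mutationColumns <- function() {
  c("population", "position", "mclass", "base_from", "base_to",
    "annotation", "gene", "appearance_time", "fate", "is_associated")
}

.mclasses <- c("point", "indel", "sv")
.annotations <- c("synonymous", "missense", "nonsense", "noncoding",
                  "indel", "sv")
.fates <- c("fixed", "extinct", "polymorphic")
.bases <- c("A", "C", "G", "T")

#' Validate an annotated mutation table
#'
#' Enforces the record invariants: recognized class/annotation/fate labels,
#' base changes present for point mutations only (ordered pairs of distinct
#' bases), protein-level annotations only on point mutations, and
#' non-negative appearance times. All violations are reported together with
#' their row numbers.
#'
#' @param muts A mutation `data.frame` (see [mutationColumns()]).
#' @return The validated table, invisibly usable; errors on any violation.
#' @export
validateMutations <- function(muts) {
  miss <- setdiff(mutationColumns(), names(muts))
  if (length(miss))
    stop("mutation table missing required columns: ",
         paste(miss, collapse = ", "))
  bad <- list()
  note <- function(rows, what) {
    if (length(rows))
      bad[[length(bad) + 1]] <<- paste0(what, " (rows ",
        paste(utils::head(rows, 5), collapse = ","),
        if (length(rows) > 5) ",..." else "", ")")
  }
  note(which(!muts$mclass %in% .mclasses),
       paste0("invalid mclass value(s): ",
              paste(unique(setdiff(muts$mclass, .mclasses)), collapse = ", ")))
  note(which(!muts$annotation %in% .annotations),
       paste0("invalid annotation value(s): ",
              paste(unique(setdiff(muts$annotation, .annotations)),
                    collapse = ", ")))
  note(which(!muts$fate %in% .fates),
       paste0("invalid fate value(s): ",
              paste(unique(setdiff(muts$fate, .fates)), collapse = ", ")))
  has_bc <- !is.na(muts$base_from) & !is.na(muts$base_to) &
    muts$base_from != "" & muts$base_to != ""
  is_pt <- muts$mclass == "point"
  note(which(is_pt & !has_bc), "point mutation without base change")
  note(which(!is_pt & has_bc), "base change on non-point mutation")
  ok_bc <- has_bc & muts$base_from %in% .bases & muts$base_to %in% .bases &
    muts$base_from != muts$base_to
  note(which(has_bc & !ok_bc), "base change not an ordered pair of distinct bases")
  note(which(muts$annotation %in% c("synonymous", "missense", "nonsense") &
               !is_pt), "protein-coding annotation on non-point mutation")
  note(which(is.na(muts$appearance_time) | muts$appearance_time < 0),
       "appearance_time missing or negative")
  note(which(is.na(muts$position) | muts$position < 1),
       "position missing or < 1")
  if (length(bad))
    stop("invalid mutation table:\n  ", paste(unlist(bad), collapse = "\n  "))
  muts
}

#' Read an annotated mutation table
#'
#' Reads the native tab-separated dialect (UTF-8, header required; see
#' [mutationColumns()]) and validates every record. Empty `base_from` /
#' `base_to` fields become `NA`.
#'
#' @param path Path to the TSV file.
#' @return A validated mutation `data.frame`.
#' @export
readMutations <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""),
                         colClasses = c(population = "character",
                                        gene = "character"))
  miss <- setdiff(mutationColumns(), names(m))
  if (length(miss))
    stop("mutation table ", path, " missing required columns: ",
         paste(miss, collapse = ", "))
  m$is_associated <- as.logical(m$is_associated)
  validateMutations(m[, mutationColumns()])
}

#' Write an annotated mutation table
#'
#' @param muts A validated mutation `data.frame`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeMutations <- function(muts, path) {
  validateMutations(muts)
  utils::write.table(muts[, mutationColumns()], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' The six strand-symmetric point-mutation classes
#'
#' @return Character vector of the six class labels in canonical order.
#' @export
spectrumClasses <- function() {
  c("A:T->C:G", "A:T->G:C", "A:T->T:A", "G:C->A:T", "G:C->T:A", "G:C->C:G")
}

#' Fold base changes into the six-class point-mutation spectrum
#'
#' Because mutations on the two DNA strands are indistinguishable in the
#' data, the 12 ordered base pairs fold into six strand-symmetric classes:
#' a change and its complement map to the same class (e.g. `T->G` and
#' `A->C` are both `A:T->C:G`, the transversion characteristic of mutT
#' loss).
#'
#' @param base_from,base_to Character vectors of single bases (A/C/G/T);
#'   pairs must be distinct.
#' @return Factor with levels [spectrumClasses()].
#' @export
classifySpectrum <- function(base_from, base_to) {
  if (length(base_from) != length(base_to))
    stop("base_from and base_to must have equal length")
  ok <- base_from %in% .bases & base_to %in% .bases & base_from != base_to
  if (any(!ok))
    stop("base changes must be ordered pairs of distinct bases (A/C/G/T); ",
         "offending values: ",
         paste(unique(paste0(base_from[!ok], "->", base_to[!ok])),
               collapse = ", "))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- base_from %in% c("T", "C")
  f <- ifelse(flip, comp[base_from], base_from)
  t <- ifelse(flip, comp[base_to], base_to)
  key <- paste0(f, t)
  map <- c(AC = "A:T->C:G", AG = "A:T->G:C", AT = "A:T->T:A",
           GA = "G:C->A:T", GT = "G:C->T:A", GC = "G:C->C:G")
  factor(unname(map[key]), levels = spectrumClasses())
}

#' Import a preprocessed metagenomic mutation table
#'
#' Adapter for externally preprocessed mutation tables whose column names
#' differ from the native dialect. `column_map` maps native column names to
#' the names found in the file; unmapped native columns are derived where
#' possible (`mclass` from `annotation`; `base_from`/`base_to` from an
#' allele column written as `"A->G"`) and filled with defaults otherwise
#' (`fate = "polymorphic"`, `is_associated = NA`).
#'
#' @param path Path to the external TSV.
#' @param column_map Named character vector: names are native columns,
#'   values are the file's columns. An `allele` entry may point at a column
#'   of `"X->Y"` base changes.
#' @return A validated mutation `data.frame`.
#' @export
importMutationTable <- function(path,
    column_map = c(population = "population", position = "position",
                   gene = "gene", annotation = "annotation",
                   appearance_time = "appearance_time", allele = "allele")) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  get <- function(native) {
    if (!native %in% names(column_map)) return(NULL)
    src <- column_map[[native]]
    if (!is.na(src) && src %in% names(raw)) raw[[src]] else NULL
  }
  n <- nrow(raw)
  out <- data.frame(
    population = as.character(get("population") %||% "unknown"),
    position = as.numeric(get("position")),
    stringsAsFactors = FALSE)
  ann <- tolower(as.character(get("annotation")))
  ann[!ann %in% .annotations] <- "noncoding"
  out$annotation <- ann
  mc <- get("mclass")
  out$mclass <- if (!is.null(mc)) mc
    else ifelse(ann == "sv", "sv", ifelse(ann == "indel", "indel", "point"))
  allele <- get("allele")
  if (!is.null(allele) && is.null(get("base_from"))) {
    parts <- regmatches(allele, regexec("^([ACGT])->([ACGT])$", allele))
    out$base_from <- vapply(parts, function(p)
      if (length(p) == 3) p[2] else NA_character_, character(1))
    out$base_to <- vapply(parts, function(p)
      if (length(p) == 3) p[3] else NA_character_, character(1))
  } else {
    out$base_from <- get("base_from") %||% rep(NA_character_, n)
    out$base_to <- get("base_to") %||% rep(NA_character_, n)
  }
  out$gene <- as.character(get("gene") %||% rep("intergenic", n))
  out$gene[is.na(out$gene)] <- "intergenic"
  out$appearance_time <- as.numeric(get("appearance_time"))
  out$fate <- as.character(get("fate") %||% rep("polymorphic", n))
  ia <- get("is_associated")
  out$is_associated <- if (is.null(ia)) rep(NA, n) else as.logical(ia)
  # point records without a parsable base change cannot enter the spectrum;
  # drop them with a message rather than mislabel them
  bad_pt <- out$mclass == "point" & (is.na(out$base_from) | is.na(out$base_to))
  if (any(bad_pt)) {
    message("dropping ", sum(bad_pt),
            " point record(s) without a parsable base change")
    out <- out[!bad_pt, , drop = FALSE]
  }
  validateMutations(out[, mutationColumns()])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
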