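#' Construct a Kabat-numbered VH variant
#'
#' A variant is an ordered residue list (Kabat position, one-letter amino
#' acid), optionally recording the parent variant it was derived from and
#' the mutations separating it from that parent.
#'
#' @param name Variant label (e.g. `"P4"`).
#' @param positions Character vector of Kabat position strings, strictly
#'   increasing in Kabat order.
#' @param aa Character vector of one-letter residues, same length.
#' @param parent Optional parent variant label.
#' @param mutations_from_parent Optional character vector of mutation strings
#'   that transform the parent into this variant.
#' @return Object of class `vh_variant`.
#' @export
vh_variant <- function(name, positions, aa, parent = NULL,
                       mutations_from_parent = character()) {
  stopifnot(length(positions) == length(aa), length(positions) > 0L)
  if (!all(aa %in% AA1)) {
    stop("invalid residues: ", paste(unique(aa[!aa %in% AA1]), collapse = ", "))
  }
  ord <- kabat_order(positions)
  if (!identical(ord, seq_along(positions))) {
    stop("positions of '", name, "' are not strictly increasing in Kabat order")
  }
  if (anyDuplicated(positions)) {
    stop("duplicated Kabat positions in '", name, "'")
  }
  structure(list(name = name,
                 positions = as.character(positions),
                 aa = as.character(aa),
                 parent = parent,
                 mutations_from_parent = as.character(mutations_from_parent)),
            class = "vh_variant")
}

#' @export
print.vh_variant <- function(x, ...) {
  cat("<vh_variant ", x$name, ": ", length(x$positions), " residues",
      if (!is.null(x$parent)) paste0(", parent ", x$parent), ">\n", sep = "")
  if (length(x$mutations_from_parent)) {
    cat("  mutations: ", paste(x$mutations_from_parent, collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Linear amino-acid sequence of a variant
#'
#' @param variant `vh_variant`.
#' @return Single string; Kabat numbering gaps are ignored.
#' @export
vh_sequence <- function(variant) paste(variant$aa, collapse = "")

#' Apply mutations to a variant
#'
#' Each mutation's position must exist in the sequence and carry the
#' mutation's from-residue; applying a mutation and then its reverse is the
#' identity. Used to materialize the maturation lineage and reversion
#' constructs.
#'
#' @param variant `vh_variant`.
#' @param muts List/vector of mutation strings or `vh_mutation`s.
#' @param name Name for the derived variant; default appends the mutations.
#' @return New `vh_variant` with `parent = variant$name`.
#' @export
apply_mutations <- function(variant, muts, name = NULL) {
  stopifnot(inherits(variant, "vh_variant"))
  muts <- lapply(muts, as_mutation)
  aa <- variant$aa
  for (m in muts) {
    pos <- format(m$position)
    i <- match(pos, variant$positions)
    if (is.na(i)) {
      stop("position ", pos, " absent from variant '", variant$name, "'")
    }
    if (aa[i] != m$from_aa) {
      stop("mutation ", format(m), ": expected ", m$from_aa, " at ", pos,
           " but found ", aa[i])
    }
    aa[i] <- m$to_aa
  }
  if (is.null(name)) {
    tag <- paste(vapply(muts, format, character(1)), collapse = "+")
    name <- if (nzchar(tag)) paste0(variant$name, "+", tag) else variant$name
  }
  vh_variant(name, variant$positions, aa, parent = variant$name,
             mutations_from_parent = vapply(muts, format, character(1)))
}

#' Scan for N-linked glycosylation sequons
#'
#' Finds every N-X-S/T motif with X != P in the linear residue string
#' (Kabat numbering gaps are ignored: glycosylation is sequence-local).
#'
#' @param variant `vh_variant`.
#' @return Data frame with one row per hit: `position` (Kabat position of
#'   the Asn), `triplet`, `index` (linear index of the Asn).
#' @export
find_sequons <- function(variant) {
  stopifnot(inherits(variant, "vh_variant"))
  aa <- variant$aa
  n <- length(aa)
  hits <- integer(0)
  if (n >= 3L) {
    for (i in seq_len(n - 2L)) {
      if (aa[i] == "N" && aa[i + 1L] != "P" && aa[i + 2L] %in% c("S", "T")) {
        hits <- c(hits, i)
      }
    }
  }
  data.frame(position = variant$positions[hits],
             triplet = vapply(hits, function(i) paste(aa[i:(i + 2L)], collapse = ""),
                              character(1)),
             index = hits,
             stringsAsFactors = FALSE)
}

#' Default CDR definitions
#'
#' Standard Kabat heavy-chain CDR boundaries plus the non-canonical CDR4
#' loop at residues 71-78. The CDR1-3 bounds are the standard Kabat
#' definitions, shipped as an overridable configuration
#' (`inst/extdata/kabat_cdr_default.json`).
#'
#' @return Named list of `c(start, end)` Kabat position strings.
#' @export
default_cdr_scheme <- function() {
  path <- system.file("extdata", "kabat_cdr_default.json", package = "vhmature")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- raw[!startsWith(names(raw), "_")]
  lapply(raw, as.character)
}

#' Annotate residues with CDR/framework regions
#'
#' Every position maps to exactly one of CDR1-CDR4 or framework. An
#' inserted position (e.g. 100d) belongs to the region of its parent
#' number's range, matching the convention that CDR3 insertions 100a-100k
#' are CDR3.
#'
#' @param variant `vh_variant`.
#' @param scheme Named list of inclusive `c(start, end)` Kabat ranges, as
#'   from [default_cdr_scheme()].
#' @return Named character vector mapping position string to region label.
#' @export
annotate_regions <- function(variant, scheme = default_cdr_scheme()) {
  stopifnot(inherits(variant, "vh_variant"))
  bounds <- lapply(scheme, function(r) {
    c(as_kabat_position(r[1])$number, as_kabat_position(r[2])$number)
  })
  # overlap check on the integer intervals
  nm <- names(bounds)
  for (i in seq_along(bounds)) {
    for (j in seq_len(i - 1L)) {
      if (bounds[[i]][1] <= bounds[[j]][2] && bounds[[j]][1] <= bounds[[i]][2]) {
        stop("overlapping region ranges: ", nm[i], " and ", nm[j])
      }
    }
  }
  num <- vapply(variant$positions, function(p) parse_kabat_position(p)$number,
                integer(1))
  region <- rep("framework", length(num))
  for (k in seq_along(bounds)) {
    region[num >= bounds[[k]][1] & num <= bounds[[k]][2]] <- nm[k]
  }
  stats::setNames(region, variant$positions)
}

#' Read a variant lineage from JSON
#'
#' The lineage file lists a root variant (explicit residues) and derived
#' variants given as a parent name plus mutation strings; derived variants
#' are materialized by [apply_mutations()].
#'
#' @param path JSON file. Schema: `root` = list(name, positions, aa);
#'   `derived` = list of list(name, parent, mutations).
#' @return Named list of `vh_variant`s.
#' @export
read_lineage <- function(path) {
  raw <- jsonlite::read_json(path)
  root <- vh_variant(raw$root$name, unlist(raw$root$positions),
                     unlist(raw$root$aa))
  out <- stats::setNames(list(root), root$name)
  for (d in raw$derived) {
    parent <- out[[d$parent]]
    if (is.null(parent)) {
      stop("parent '", d$parent, "' of '", d$name, "' not defined yet")
    }
    out[[d$name]] <- apply_mutations(parent, unlist(d$mutations),
                                     name = d$name)
  }
  out
}

#' Write a variant lineage to JSON
#'
#' @param lineage Named list of `vh_variant`s; the first must be the root.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_lineage <- function(lineage, path) {
  root <- lineage[[1]]
  derived <- Filter(function(v) !is.null(v$parent), lineage[-1])
  jsonlite::write_json(
    list(root = list(name = root$name, positions = root$positions, aa = root$aa),
         derived = lapply(derived, function(v) {
           list(name = v$name, parent = v$parent,
                mutations = as.list(v$mutations_from_parent))
         })),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Export a variant as FASTA plus a Kabat sidecar map
#'
#' Writes the linear sequence as FASTA and a tab-separated
#' position-to-residue map preserving the Kabat numbering that FASTA
#' cannot carry.
#'
#' @param variant `vh_variant`.
#' @param fasta_path Output FASTA file.
#' @param map_path Output TSV (`position`, `aa`); default replaces the
#'   FASTA extension with `.kabat.tsv`.
#' @return `fasta_path`, invisibly.
#' @export
write_variant_fasta <- function(variant, fasta_path,
                                map_path = sub("\\.[^.]*$", ".kabat.tsv",
                                               fasta_path)) {
  writeLines(c(paste0(">", variant$name), vh_sequence(variant)), fasta_path)
  utils::write.table(
    data.frame(position = variant$positions, aa = variant$aa),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}
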