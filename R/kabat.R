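#' Parse a Kabat position string
#'
#' Kabat heavy-chain numbering uses a positive residue number optionally
#' followed by a single lowercase insertion letter (e.g. `"82b"`, `"100d"`)
#' so that variable-length loops align across antibodies. A position with no
#' insertion letter sorts before the same number with insertion `"a"`.
#'
#' @param text Character scalar: digits optionally followed by one lowercase
#'   letter (`"45"`, `"82b"`).
#' @return An object of class `kabat_position` with fields `number`
#'   (integer) and `insertion` (single lowercase letter or `""`).
#' @examples
#' parse_kabat_position("100d")
#' @export
parse_kabat_position <- function(text) {
  if (length(text) != 1L || !is.character(text) || is.na(text)) {
    stop("Kabat position must be a single character string, got: ",
         deparse(substitute(text)))
  }
  m <- regmatches(text, regexec("^([0-9]+)([a-z]?)$", text))[[1]]
  if (length(m) == 0L) {
    stop("malformed Kabat position: '", text, "'")
  }
  number <- as.integer(m[2])
  if (is.na(number) || number < 1L) {
    stop("malformed Kabat position: '", text, "' (number must be positive)")
  }
  structure(list(number = number, insertion = m[3]),
            class = "kabat_position")
}

#' @export
format.kabat_position <- function(x, ...) paste0(x$number, x$insertion)

#' @export
print.kabat_position <- function(x, ...) {
  cat("<kabat position ", format(x), ">\n", sep = "")
  invisible(x)
}

#' Compare two Kabat positions
#'
#' Total ordering: numbers compare first; at equal numbers the empty
#' insertion code precedes `"a"`, which precedes `"b"`, and so on.
#'
#' @param a,b `kabat_position` objects or strings accepted by
#'   [parse_kabat_position()].
#' @return -1, 0 or 1 as `a` is before, equal to, or after `b`.
#' @export
kabat_compare <- function(a, b) {
  a <- as_kabat_position(a)
  b <- as_kabat_position(b)
  if (a$number != b$number) return(sign(a$number - b$number))
  # empty code ranks 0, 'a' ranks 1, ... 'z' ranks 26
  ra <- if (a$insertion == "") 0L else utf8ToInt(a$insertion) - 96L
  rb <- if (b$insertion == "") 0L else utf8ToInt(b$insertion) - 96L
  sign(ra - rb)
}

as_kabat_position <- function(x) {
  if (inherits(x, "kabat_position")) x else parse_kabat_position(x)
}

#' Order a vector of Kabat position strings
#'
#' @param positions Character vector of Kabat position strings.
#' @return Integer permutation putting `positions` in Kabat order
#'   (usable like [order()]).
#' @export
kabat_order <- function(positions) {
  parsed <- lapply(positions, parse_kabat_position)
  num <- vapply(parsed, function(p) p$number, integer(1))
  ins <- vapply(parsed, function(p) {
    if (p$insertion == "") 0L else utf8ToInt(p$insertion) - 96L
  }, integer(1))
  order(num, ins)
}

AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Parse a mutation string
#'
#' Mutations are written `<from><position><to>` with one-letter amino acid
#' codes and a Kabat position, e.g. `"E45K"` or `"G82bS"` (wild-type residue,
#' position, substituted residue).
#'
#' @param text Character scalar mutation string.
#' @return An object of class `vh_mutation` with fields `from_aa`,
#'   `position` (`kabat_position`) and `to_aa`.
#' @examples
#' parse_mutation("G82bS")
#' @export
parse_mutation <- function(text) {
  if (length(text) != 1L || !is.character(text) || is.na(text)) {
    stop("mutation must be a single character string")
  }
  m <- regmatches(text, regexec("^([A-Z])([0-9]+[a-z]?)([A-Z])$", text))[[1]]
  if (length(m) == 0L) {
    stop("malformed mutation: '", text, "'")
  }
  from_aa <- m[2]
  to_aa <- m[4]
  if (!(from_aa %in% AA1)) stop("not an amino acid: '", from_aa, "' in '", text, "'")
  if (!(to_aa %in% AA1)) stop("not an amino acid: '", to_aa, "' in '", text, "'")
  if (from_aa == to_aa) {
    stop("mutation '", text, "' has identical from/to residues")
  }
  structure(list(from_aa = from_aa,
                 position = parse_kabat_position(m[3]),
                 to_aa = to_aa),
            class = "vh_mutation")
}

#' @export
format.vh_mutation <- function(x, ...) {
  paste0(x$from_aa, format(x$position), x$to_aa)
}

#' @export
print.vh_mutation <- function(x, ...) {
  cat("<mutation ", format(x), ">\n", sep = "")
  invisible(x)
}

#' Reverse a mutation
#'
#' Swaps the from/to residues; reversing twice returns the original
#' mutation (involution). Used to turn a P-series mutation into its
#' wild-type reversion and back.
#'
#' @param mutation `vh_mutation` or mutation string.
#' @return The reversed `vh_mutation`.
#' @export
reverse_mutation <- function(mutation) {
  mutation <- as_mutation(mutation)
  structure(list(from_aa = mutation$to_aa,
                 position = mutation$position,
                 to_aa = mutation$from_aa),
            class = "vh_mutation")
}

as_mutation <- function(x) {
  if (inherits(x, "vh_mutation")) x else parse_mutation(x)
}
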