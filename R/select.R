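#' Atom selection by expression
#'
#' A small selection grammar modelled on the ones mainstream trajectory tools
#' use. Supported primaries:
#' \itemize{
#'   \item `all`, `heavy`, `hydrogen`, `water` (resnames HOH/WAT/SOL/TIP3)
#'   \item `name <id...>`, `resname <id...>`, `chain <id...>`,
#'     `element <id...>`, `serial <n...>`
#'   \item `resid <n | a:b ...>` (residue numbers as in the source file)
#'   \item `within <R> of <expr>` — atoms whose minimum Euclidean distance to
#'     any atom of the sub-selection is `<= R` (inclusive), evaluated on the
#'     system's coordinate set (or `coords` if given)
#'   \item `not`, `and`, `or` and parentheses, with the usual precedence
#'     (`not` > `and` > `or`)
#' }
#'
#' Hydrogens are identified by the element field when the source file carried
#' one, else by the leading alphabetic character of the atom name.
#'
#' @param system a `MolecularSystem`.
#' @param expression selection string.
#' @param coords optional n_atoms x 3 matrix on which `within` distances are
#'   evaluated (defaults to `system$xyz`).
#' @return an object of class `Selection`: sorted unique 1-based atom
#'   indices plus the originating expression.
#' @export
select_atoms <- function(system, expression, coords = NULL) {
  stopifnot(inherits(system, "MolecularSystem"))
  if (is.null(coords)) coords <- system$xyz
  toks <- tokenize_selection(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  mask <- parse_or(st, system, coords)
  if (st$pos <= length(st$toks)) {
    stop(sprintf("selection syntax error near token %d ('%s') in: %s",
                 st$pos, st$toks[st$pos], expression))
  }
  idx <- which(mask)
  if (length(idx) == 0L) {
    warning("selection matched no atoms: ", expression)
  }
  structure(list(indices = idx, expression = expression),
            class = "Selection")
}

#' @export
print.Selection <- function(x, ...) {
  cat(sprintf("<Selection> %d atoms: %s\n", length(x$indices), x$expression))
  invisible(x)
}

selection_indices <- function(system, sel, coords = NULL) {
  if (inherits(sel, "Selection")) return(sel$indices)
  if (is.character(sel)) return(select_atoms(system, sel, coords)$indices)
  as.integer(sel)
}

tokenize_selection <- function(expression) {
  if (!is.character(expression) || length(expression) != 1L || is.na(expression)) {
    stop("selection expression must be a single string")
  }
  spaced <- gsub("\\)", " ) ", gsub("\\(", " ( ", expression))
  toks <- strsplit(trimws(spaced), "[[:space:]]+")[[1]]
  toks[toks != ""]
}

sel_keywords <- c("and", "or", "not", "(", ")", "all", "none", "heavy",
                  "hydrogen", "water", "name", "resname", "resid", "chain",
                  "element", "serial", "within", "of")

peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_
advance <- function(st) { st$pos <- st$pos + 1L; st$toks[st$pos - 1L] }
expect <- function(st, tok) {
  got <- advance(st)
  if (is.na(got) || got != tok) {
    stop(sprintf("selection syntax error at token %d: expected '%s', got '%s'",
                 st$pos - 1L, tok, if (is.na(got)) "<end>" else got))
  }
  got
}

parse_or <- function(st, system, coords) {
  left <- parse_and(st, system, coords)
  while (!is.na(peek(st)) && peek(st) == "or") {
    advance(st)
    left <- left | parse_and(st, system, coords)
  }
  left
}

parse_and <- function(st, system, coords) {
  left <- parse_not(st, system, coords)
  while (!is.na(peek(st)) && peek(st) == "and") {
    advance(st)
    left <- left & parse_not(st, system, coords)
  }
  left
}

parse_not <- function(st, system, coords) {
  if (!is.na(peek(st)) && peek(st) == "not") {
    advance(st)
    return(!parse_not(st, system, coords))
  }
  parse_primary(st, system, coords)
}

take_values <- function(st) {
  vals <- character(0)
  while (!is.na(peek(st)) && !(peek(st) %in% sel_keywords)) {
    vals <- c(vals, advance(st))
  }
  if (length(vals) == 0L) {
    stop("selection syntax error at token ", st$pos, ": expected value list")
  }
  vals
}

parse_primary <- function(st, system, coords) {
  at <- system$atoms
  tok <- advance(st)
  if (is.na(tok)) stop("selection syntax error: unexpected end of expression")
  switch(tok,
    "(" = {
      inner <- parse_or(st, system, coords)
      expect(st, ")")
      inner
    },
    all = rep(TRUE, nrow(at)),
    none = rep(FALSE, nrow(at)),
    heavy = at$heavy,
    hydrogen = !at$heavy,
    water = at$resname %in% c("HOH", "WAT", "SOL", "TIP3"),
    name = at$name %in% take_values(st),
    resname = at$resname %in% take_values(st),
    chain = at$chain %in% take_values(st),
    element = toupper(at$element) %in% toupper(take_values(st)),
    serial = at$serial %in% as.integer(take_values(st)),
    resid = {
      vals <- take_values(st)
      ids <- integer(0)
      for (v in vals) {
        if (grepl(":", v, fixed = TRUE)) {
          ab <- as.integer(strsplit(v, ":", fixed = TRUE)[[1]])
          if (anyNA(ab) || length(ab) != 2L) {
            stop("bad resid range in selection: ", v)
          }
          ids <- c(ids, seq(ab[1], ab[2]))
        } else {
          id <- suppressWarnings(as.integer(v))
          if (is.na(id)) stop("bad resid in selection: ", v)
          ids <- c(ids, id)
        }
      }
      at$resid %in% ids
    },
    within = {
      r <- suppressWarnings(as.numeric(advance(st)))
      if (!is.finite(r) || r < 0) {
        stop("selection syntax error: 'within' needs a nonnegative radius")
      }
      expect(st, "of")
      ref_mask <- parse_not(st, system, coords)
      within_mask(coords, ref_mask, r)
    },
    stop(sprintf("selection syntax error at token %d: unknown keyword '%s'",
                 st$pos - 1L, tok))
  )
}

# inclusive <= r minimum-distance test of every atom against the reference set
within_mask <- function(coords, ref_mask, r) {
  ref <- coords[ref_mask, , drop = FALSE]
  n <- nrow(coords)
  if (nrow(ref) == 0L) return(rep(FALSE, n))
  mask <- rep(FALSE, n)
  r2 <- r * r
  # block over reference atoms to keep memory bounded
  for (j in seq_len(nrow(ref))) {
    d2 <- (coords[, 1] - ref[j, 1])^2 + (coords[, 2] - ref[j, 2])^2 +
      (coords[, 3] - ref[j, 3])^2
    mask <- mask | (d2 <= r2)
    if (all(mask)) break
  }
  mask
}
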