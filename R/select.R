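#' Atom selections
#'
#' A small selection grammar over the atom table. Primitives:
#' \itemize{
#'   \item `resid A:B` or `resid 5 7 9` — author residue numbers (`resseq`)
#'   \item `resname DOPC DOPS`, `name CA P`, `element O`, `chain A`
#'   \item `protein`, `lipid`, `water`, `heavy`, `backbone`, `all`
#'   \item `sidechain-heavy` — side-chain heavy atoms; for glycine this is
#'     exactly the CA atom
#'   \item `phosphorus` — phosphorus reference atoms
#'   \item `water-oxygen` — water oxygen atoms
#'   \item `headgroup-heavy` — heavy atoms of lipid head groups (atom names
#'     configurable via `options(memhelix.headgroup_names = ...)`)
#' }
#' combined with `and`, `or`, `not` and parentheses (`not` binds tightest).
#'
#' @param system an `mh_system`.
#' @param expression selection expression (see Details).
#' @return integer vector of atom indices (class `mh_selection`) with the
#'   expression kept as an attribute. An empty result warns but is returned.
#' @examples
#' sys <- build_ideal_helix()
#' select_atoms(sys, "resid 5:25 and name CA")
#' @export
select_atoms <- function(system, expression) {
  toks <- tokenize_selection(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L
  mask <- parse_or(st, system)
  if (st$pos <= length(st$toks))
    stop("selection syntax error near '", st$toks[st$pos], "'", call. = FALSE)
  idx <- which(mask)
  if (length(idx) == 0L)
    warning("selection '", expression, "' matched no atoms", call. = FALSE)
  structure(idx, expression = expression, class = c("mh_selection", "integer"))
}

#' @export
print.mh_selection <- function(x, ...) {
  cat(sprintf("<mh_selection> %d atom(s): %s\n", length(x),
              attr(x, "expression") %||% "<indices>"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_selection <- function(idx, expression = "<indices>") {
  structure(as.integer(idx), expression = expression,
            class = c("mh_selection", "integer"))
}

tokenize_selection <- function(expression) {
  if (!is.character(expression) || length(expression) != 1L)
    stop("selection expression must be a single string", call. = FALSE)
  x <- gsub("\\(", " ( ", expression)
  x <- gsub("\\)", " ) ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1L]]
  if (length(toks) == 0L) stop("empty selection expression", call. = FALSE)
  toks
}

peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_
advance <- function(st) { st$pos <- st$pos + 1L; invisible(NULL) }

parse_or <- function(st, system) {
  left <- parse_and(st, system)
  while (!is.na(peek(st)) && tolower(peek(st)) == "or") {
    advance(st)
    left <- left | parse_and(st, system)
  }
  left
}

parse_and <- function(st, system) {
  left <- parse_factor(st, system)
  while (!is.na(peek(st)) && tolower(peek(st)) == "and") {
    advance(st)
    left <- left & parse_factor(st, system)
  }
  left
}

parse_factor <- function(st, system) {
  tok <- peek(st)
  if (is.na(tok)) stop("unexpected end of selection expression", call. = FALSE)
  if (tolower(tok) == "not") {
    advance(st)
    return(!parse_factor(st, system))
  }
  if (tok == "(") {
    advance(st)
    inner <- parse_or(st, system)
    if (is.na(peek(st)) || peek(st) != ")")
      stop("unbalanced parentheses in selection", call. = FALSE)
    advance(st)
    return(inner)
  }
  parse_primitive(st, system)
}

.keywords <- c("and", "or", "not", "(", ")", "resid", "resname", "name",
               "element", "chain", "protein", "lipid", "water", "heavy",
               "backbone", "all", "sidechain-heavy", "phosphorus",
               "water-oxygen", "headgroup-heavy")

collect_values <- function(st) {
  vals <- character(0)
  while (!is.na(peek(st)) && !(tolower(peek(st)) %in% .keywords)) {
    vals <- c(vals, peek(st)); advance(st)
  }
  if (length(vals) == 0L)
    stop("selection keyword needs at least one value", call. = FALSE)
  vals
}

parse_primitive <- function(st, system) {
  at <- system$atoms
  tok <- tolower(peek(st))
  switch(tok,
    "resid" = { advance(st); resseq_mask(at, collect_values(st)) },
    "resname" = { advance(st); at$resname %in% toupper(collect_values(st)) },
    "name" = { advance(st); at$name %in% toupper(collect_values(st)) },
    "element" = { advance(st)
      toupper(at$element) %in% toupper(collect_values(st)) },
    "chain" = { advance(st); at$chain %in% collect_values(st) },
    "protein" = { advance(st); at$resname %in% names(.aa_three_to_one) },
    "lipid" = { advance(st); at$resname %in% lipid_resnames() },
    "water" = { advance(st); at$resname %in% water_resnames() },
    "heavy" = { advance(st); !is_hydrogen(at) },
    "backbone" = { advance(st)
      at$resname %in% names(.aa_three_to_one) &
        at$name %in% c("N", "CA", "C", "O", "OXT") },
    "all" = { advance(st); rep(TRUE, nrow(at)) },
    "sidechain-heavy" = { advance(st); sidechain_heavy_mask(at) },
    "phosphorus" = { advance(st)
      toupper(at$element) == "P" | at$name == "P" },
    "water-oxygen" = { advance(st)
      at$resname %in% water_resnames() & toupper(at$element) == "O" },
    "headgroup-heavy" = { advance(st)
      at$resname %in% lipid_resnames() & !is_hydrogen(at) &
        at$name %in% getOption("memhelix.headgroup_names", c("P", "HG")) },
    stop("unknown selection keyword '", peek(st), "'", call. = FALSE)
  )
}

resseq_mask <- function(at, vals) {
  want <- integer(0)
  for (v in vals) {
    if (grepl("^-?[0-9]+:[-]?[0-9]+$", v)) {
      ab <- as.integer(strsplit(v, ":")[[1L]])
      want <- c(want, seq(ab[1L], ab[2L]))
    } else {
      n <- suppressWarnings(as.integer(v))
      if (is.na(n)) stop("bad resid value '", v, "'", call. = FALSE)
      want <- c(want, n)
    }
  }
  at$resseq %in% want
}

# Side-chain heavy atoms: protein heavy atoms that are not backbone, except
# glycine where the side chain resolves to the CA atom.
sidechain_heavy_mask <- function(at) {
  prot <- at$resname %in% names(.aa_three_to_one)
  bb <- at$name %in% c("N", "CA", "C", "O", "OXT")
  (prot & !bb & !is_hydrogen(at)) |
    (prot & at$resname == "GLY" & at$name == "CA")
}

lipid_resnames <- function()
  getOption("memhelix.lipid_resnames", c("DOPC", "DOPS", "POPC", "POPS",
                                         "DPPC", "DOPE"))
water_resnames <- function()
  getOption("memhelix.water_resnames", c("SOL", "HOH", "WAT", "TIP3", "SPC"))

#' Selection set algebra
#'
#' @param a,b `mh_selection` objects (or integer index vectors).
#' @param system an `mh_system` (needed by [selection_complement()]).
#' @return an `mh_selection`.
#' @export
selection_union <- function(a, b)
  as_selection(sort(union(as.integer(a), as.integer(b))), "<union>")

#' @rdname selection_union
#' @export
selection_intersect <- function(a, b)
  as_selection(sort(intersect(as.integer(a), as.integer(b))), "<intersect>")

#' @rdname selection_union
#' @export
selection_complement <- function(a, system)
  as_selection(setdiff(seq_len(nrow(system$atoms)), as.integer(a)),
               "<complement>")
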