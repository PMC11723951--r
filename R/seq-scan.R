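#' Motif grammars for HP1 chromoshadow-domain ligand scanning
#'
#' Each grammar is expanded into one or more fixed-length templates: a
#' template is a vector of position constraints, where `"."` matches any of
#' the 20 standard residues (and `X`), and a string such as `"VI"` matches
#' only those residues. Variable-gap grammars (His-Cys, phi2 and the
#' amphibian His-Cys variant) contribute one template per realized gap
#' length, so all alternative spans are enumerated.
#'
#' Grammars: phi1 `[VI]-x-L`; His-Cys `H-x4-C-x3/4-C` (amphibian variant
#' `H-x3/4-C-x13/14-C`); phi2 `L-x5/6-V-x-L`; phi3 `L-x5-V-x-L`; PxVxL
#' `P-x-V-x-L`. The motif's central "0" residue (the pocket-engaging
#' position of the five-residue chromoshadow core) is defined for the
#' hydrophobic classes and reported as `core_zero_pos`.
#'
#' @param classes Character vector of grammar names.
#' @return Named list: per class, a list of templates (character vectors).
#' @export
motif_grammar <- function(classes = c("phi1", "hiscys", "hiscys_amphibian",
                                      "phi2", "phi3", "pxvxl")) {
  tmpl <- function(...) {
    parts <- list(...)
    out <- list(character(0))
    for (p in parts) {
      if (is.numeric(p)) {
        out <- unlist(lapply(out, function(t)
          lapply(p, function(n) c(t, rep(".", n)))), recursive = FALSE)
      } else {
        out <- lapply(out, function(t) c(t, p))
      }
    }
    out
  }
  all <- list(
    phi1 = tmpl("VI", 1, "L"),
    hiscys = tmpl("H", 4, "C", 3:4, "C"),
    hiscys_amphibian = tmpl("H", 3:4, "C", 13:14, "C"),
    phi2 = tmpl("L", 5:6, "V", 1, "L"),
    phi3 = tmpl("L", 5, "V", 1, "L"),
    pxvxl = tmpl("P", 1, "V", 1, "L")
  )
  unknown <- setdiff(classes, names(all))
  if (length(unknown)) {
    abort(sprintf("unknown motif class(es): %s", paste(unknown, collapse = ", ")),
          class = "hrdquant_unknown_motif_class")
  }
  all[classes]
}

# Offset of the central "0" core residue within a matched template, or NA.
core_zero_offset <- function(class, span) {
  switch(class,
    phi1 = 0L,            # V/I occupies the 0 position, L is +2
    phi2 = span - 3L,     # ...V-x-L: V at 0, L at +2
    phi3 = span - 3L,
    pxvxl = 2L,           # P-x-V-x-L: V at 0
    NA_integer_
  )
}

template_regex <- function(template) {
  paste(vapply(template, function(p) {
    if (p == ".") "." else paste0("[", p, "]")
  }, character(1)), collapse = "")
}

#' Scan a protein sequence for chromoshadow-ligand motifs
#'
#' Enumerates every match of the requested motif grammars, including
#' overlapping matches and all alternative spans of variable-gap grammars.
#' `X` is permitted in the input and matches wildcard positions only, never
#' a constrained position.
#'
#' @param sequence Protein sequence (single string over the 20-letter
#'   alphabet, `X` allowed).
#' @param classes Motif classes to scan (see [motif_grammar()]).
#' @return Tibble with columns `motif_class`, `start`, `end` (1-based,
#'   inclusive), `matched` and `core_zero_pos`, sorted by `start` then
#'   class. Empty sequence yields an empty tibble.
#' @export
scan_motifs <- function(sequence,
                        classes = c("phi1", "hiscys", "phi2", "phi3", "pxvxl")) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (nchar(sequence) == 0) {
    return(tibble(motif_class = character(), start = integer(),
                  end = integer(), matched = character(),
                  core_zero_pos = integer()))
  }
  sequence <- toupper(sequence)
  bad <- setdiff(strsplit(sequence, "")[[1]], c(AA20, "X"))
  if (length(bad)) {
    abort(sprintf("illegal residue character(s): %s", paste(unique(bad), collapse = ", ")),
          class = "hrdquant_bad_sequence")
  }

  grammars <- motif_grammar(classes)
  hits <- purrr::imap(grammars, function(templates, class) {
    purrr::map(templates, function(t) {
      span <- length(t)
      pat <- paste0("(?=", template_regex(t), ")")
      m <- gregexpr(pat, sequence, perl = TRUE)[[1]]
      if (m[1] == -1) return(NULL)
      starts <- as.integer(m)
      tibble(
        motif_class = class, start = starts, end = starts + span - 1L,
        matched = substring(sequence, starts, starts + span - 1L),
        core_zero_pos = starts + core_zero_offset(class, span)
      )
    })
  })
  out <- dplyr::bind_rows(unlist(hits, recursive = FALSE))
  if (!nrow(out)) {
    return(tibble(motif_class = character(), start = integer(),
                  end = integer(), matched = character(),
                  core_zero_pos = integer()))
  }
  out <- dplyr::distinct(out)
  dplyr::arrange(out, .data$start, match(.data$motif_class, names(grammars)),
                 .data$end)
}
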