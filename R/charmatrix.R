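# ---------------------------------------------------------------------------
# Discrete character matrices: TNT/NEXUS I/O, supraspecific-OTU scoring,
# Fitch parsimony length, and ensemble fit indices (no tree search).
# ---------------------------------------------------------------------------

#' Read a discrete character matrix (TNT xread or NEXUS)
#'
#' Cells are small non-negative integer states. `[01]`, `(01)` or `{0 1}`
#' mark polymorphic cells; `?` or `-` mark missing data. Missing cells enter
#' downstream computations as the full set of states observed for that
#' character.
#'
#' @param source file path or the matrix text itself.
#' @return an object of class `char_matrix` with elements `taxa` (labels),
#'   `nchar`, `cells` (list-matrix of integer state vectors; missing cells
#'   are empty), `missing` (logical matrix), and `observed` (list of observed
#'   states per character).
#' @export
read_char_matrix <- function(source) {
  txt <- if (length(source) == 1 && !grepl("\n", source) &&
             !grepl(";", source) && file.exists(source)) {
    paste(readLines(source, warn = FALSE), collapse = "\n")
  } else {
    paste(source, collapse = "\n")
  }
  if (grepl("^\\s*#NEXUS", txt, ignore.case = TRUE)) {
    parse_nexus_matrix(txt)
  } else if (grepl("xread", txt, ignore.case = TRUE)) {
    parse_tnt_matrix(txt)
  } else {
    stop("unrecognized matrix format: expected TNT 'xread' or '#NEXUS'")
  }
}

#' @noRd
parse_state_string <- function(s, taxon) {
  chars <- strsplit(s, "")[[1]]
  out <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t")) {
      i <- i + 1L
    } else if (ch %in% c("?", "-")) {
      out[[length(out) + 1L]] <- integer(0)  # missing sentinel
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      out[[length(out) + 1L]] <- as.integer(ch)
      i <- i + 1L
    } else if (ch %in% c("[", "(", "{")) {
      close <- c("[" = "]", "(" = ")", "{" = "}")[ch]
      j <- i + 1L
      states <- integer(0)
      while (j <= length(chars) && chars[j] != close) {
        if (grepl("[0-9]", chars[j])) states <- c(states, as.integer(chars[j]))
        else if (!chars[j] %in% c(" ", "\t"))
          stop("unknown symbol '", chars[j], "' inside polymorphism for ",
               taxon)
        j <- j + 1L
      }
      if (j > length(chars)) stop("unclosed polymorphism bracket for ", taxon)
      if (!length(states)) stop("empty polymorphism set for ", taxon)
      out[[length(out) + 1L]] <- sort(unique(states))
      i <- j + 1L
    } else {
      stop("unknown symbol '", ch, "' in row for ", taxon)
    }
  }
  out
}

#' @noRd
build_char_matrix <- function(taxa, rows, nchar_expect = NULL) {
  lengths_ <- vapply(rows, length, 1L)
  if (length(unique(lengths_)) != 1)
    stop("row length mismatch: ", paste(unique(lengths_), collapse = " vs "))
  k <- lengths_[1]
  if (!is.null(nchar_expect) && k != nchar_expect)
    stop("matrix declares ", nchar_expect, " characters but rows have ", k)
  if (anyDuplicated(taxa))
    stop("duplicate taxon label(s): ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  n <- length(taxa)
  cells <- matrix(vector("list", n * k), n, k)
  missing <- matrix(FALSE, n, k)
  for (i in seq_len(n)) for (j in seq_len(k)) {
    st <- rows[[i]][[j]]
    cells[[i, j]] <- st
    missing[i, j] <- length(st) == 0
  }
  observed <- lapply(seq_len(k), function(j)
    sort(unique(unlist(cells[, j]))))
  for (j in seq_len(k)) {
    if (!length(observed[[j]])) observed[[j]] <- 0L
    if (max(observed[[j]]) > 9L || length(observed[[j]]) > 10L)
      stop("more than 10 states in character ", j)
  }
  structure(list(taxa = taxa, nchar = k, cells = cells,
                 missing = missing, observed = observed),
            class = "char_matrix")
}

#' @noRd
parse_tnt_matrix <- function(txt) {
  txt <- gsub("'[^']*'", "", txt)           # strip quoted comments
  body <- sub(".*?xread", "", txt, ignore.case = TRUE)
  body <- sub(";.*", "", body)
  lines <- trimws(strsplit(body, "\n")[[1]])
  lines <- lines[nzchar(lines)]
  hdr <- suppressWarnings(as.integer(strsplit(lines[1], "\\s+")[[1]]))
  if (length(hdr) != 2 || anyNA(hdr))
    stop("TNT header must give '<nchar> <ntax>'")
  nchar_d <- hdr[1]; ntax_d <- hdr[2]
  rows <- lines[-1]
  if (length(rows) != ntax_d)
    stop("expected ", ntax_d, " taxon rows, found ", length(rows))
  taxa <- sub("\\s.*", "", rows)
  seqs <- sub("^\\S+\\s+", "", rows)
  parsed <- Map(parse_state_string, seqs, taxa)
  build_char_matrix(taxa, unname(parsed), nchar_d)
}

#' @noRd
parse_nexus_matrix <- function(txt) {
  txt <- gsub("\\[[^]0-9][^]]*\\]", "", txt)  # NEXUS comments, not polymorphism
  ntax <- as.integer(sub(".*ntax\\s*=\\s*([0-9]+).*", "\\1", txt,
                         ignore.case = TRUE))
  nch <- as.integer(sub(".*nchar\\s*=\\s*([0-9]+).*", "\\1", txt,
                        ignore.case = TRUE))
  m <- regmatches(txt, regexpr("matrix.*?;", txt, ignore.case = TRUE))
  if (!length(m)) stop("no MATRIX block found in NEXUS input")
  body <- sub(";$", "", sub("^matrix", "", m, ignore.case = TRUE))
  lines <- trimws(strsplit(body, "\n")[[1]])
  lines <- lines[nzchar(lines)]
  taxa <- sub("\\s.*", "", lines)
  seqs <- sub("^\\S+\\s+", "", lines)
  parsed <- Map(parse_state_string, seqs, taxa)
  build_char_matrix(taxa, unname(parsed), nch)
}

#' Write a character matrix in TNT xread format
#'
#' @param m a `char_matrix`.
#' @param file optional path; when `NULL` the text is returned.
#' @return the matrix text, invisibly when written to file.
#' @export
write_char_matrix <- function(m, file = NULL) {
  stopifnot(inherits(m, "char_matrix"))
  fmt_cell <- function(st, miss) {
    if (miss) "?"
    else if (length(st) == 1) as.character(st)
    else paste0("[", paste(st, collapse = ""), "]")
  }
  rows <- vapply(seq_along(m$taxa), function(i) {
    cells <- vapply(seq_len(m$nchar), function(j)
      fmt_cell(m$cells[[i, j]], m$missing[i, j]), "")
    paste0(m$taxa[i], "\t", paste(cells, collapse = ""))
  }, "")
  txt <- paste0("xread\n", m$nchar, " ", length(m$taxa), "\n",
                paste(rows, collapse = "\n"), "\n;")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' @export
print.char_matrix <- function(x, ...) {
  cat("Character matrix:", length(x$taxa), "taxa x", x$nchar, "characters;",
      sum(x$missing), "missing cell(s),",
      sum(vapply(x$cells, length, 1L) > 1), "polymorphic cell(s)\n")
  invisible(x)
}

#' Effective tip state sets, with missing cells expanded
#' @noRd
effective_cells <- function(m) {
  out <- m$cells
  for (j in seq_len(m$nchar)) {
    miss <- which(m$missing[, j])
    for (i in miss) out[[i, j]] <- m$observed[[j]]
  }
  out
}

# ---------------------------------------------------------------------------
# Supraspecific-OTU scoring
# ---------------------------------------------------------------------------

#' Score a supraspecific OTU from member species scores
#'
#' Majority-style rule for collapsing the scores of five member species into
#' a single terminal: for binary characters, a sum of 0 or 1 scores the OTU
#' 0; a sum of 2 or 3 scores it polymorphic `{0,1}`; a sum of 4 or 5 scores
#' it 1. For a non-binary character the rule applies only when at least four
#' of the five members agree, in which case the shared state is used.
#'
#' @param member_scores integer vector of 5 member-species scores.
#' @return integer vector: the OTU's state set.
#' @export
score_supraspecific_otu <- function(member_scores) {
  if (length(member_scores) != 5 || anyNA(member_scores))
    stop("need exactly 5 non-missing member scores")
  member_scores <- as.integer(member_scores)
  if (all(member_scores %in% c(0L, 1L))) {
    s <- sum(member_scores)
    if (s <= 1) return(0L)
    if (s <= 3) return(c(0L, 1L))
    return(1L)
  }
  tab <- table(member_scores)
  if (max(tab) >= 4) return(as.integer(names(tab)[which.max(tab)]))
  stop("non-binary scores without a 4/5 majority cannot be collapsed")
}

# ---------------------------------------------------------------------------
# Fitch parsimony scoring
# ---------------------------------------------------------------------------

#' @noRd
tip_bitmasks <- function(m) {
  eff <- effective_cells(m)
  n <- length(m$taxa)
  masks <- matrix(0L, n, m$nchar)
  for (i in seq_len(n)) for (j in seq_len(m$nchar))
    masks[i, j] <- sum(bitwShiftL(1L, eff[[i, j]]))
  masks
}

#' Fitch parsimony length of a character matrix on a fixed topology
#'
#' Minimum number of unordered state changes per character by the Fitch
#' set recursion: at each internal node the child sets are intersected; an
#' empty intersection is replaced by the union and counts one step.
#' Polymorphic cells enter as their state set; missing cells as all observed
#' states of the character. Branch lengths are ignored.
#'
#' @param tree a rooted `phylo` or `timetree` whose tips match `m$taxa`.
#' @param m a `char_matrix`.
#' @return list with `per_character` (integer vector) and `total`.
#' @export
fitch_length <- function(tree, m) {
  phy <- as_phylo(tree)
  stopifnot(inherits(m, "char_matrix"))
  if (!setequal(phy$tip.label, m$taxa))
    stop("tree tips and matrix taxa do not match")
  n <- ape::Ntip(phy)
  N <- n + phy$Nnode
  masks <- matrix(0L, N, m$nchar)
  masks[seq_len(n), ] <- tip_bitmasks(m)[match(phy$tip.label, m$taxa), ,
                                         drop = FALSE]
  steps <- integer(m$nchar)
  seen <- logical(N)
  eo <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    p <- eo[k, 1]; ch <- eo[k, 2]
    if (!seen[p]) {
      masks[p, ] <- masks[ch, ]
      seen[p] <- TRUE
    } else {
      inter <- bitwAnd(masks[p, ], masks[ch, ])
      hit <- inter != 0L
      steps <- steps + !hit
      masks[p, ] <- ifelse(hit, inter, bitwOr(masks[p, ], masks[ch, ]))
    }
  }
  list(per_character = steps, total = sum(steps))
}

#' Per-character minimum steps (minimum over all trees)
#'
#' The smallest number of changes any tree can achieve: one less than the
#' minimum number of states needed to intersect every non-missing tip's
#' state set (a minimum hitting set, exact by subset enumeration).
#' @noRd
min_steps_per_character <- function(m) {
  eff <- effective_cells(m)
  vapply(seq_len(m$nchar), function(j) {
    sets <- eff[m$missing[, j] == FALSE, j]
    if (!length(sets)) return(0L)
    states <- m$observed[[j]]
    tip_masks <- vapply(sets, function(s) sum(bitwShiftL(1L, s)), 0)
    for (size in seq_along(states)) {
      combs <- combn(seq_along(states), size)
      for (c_i in seq_len(ncol(combs))) {
        hmask <- sum(bitwShiftL(1L, states[combs[, c_i]]))
        if (all(bitwAnd(tip_masks, hmask) != 0)) return(size - 1L)
      }
    }
    length(states) - 1L
  }, 0L)
}

#' Per-character maximum steps (star-tree length)
#'
#' Star-tree parsimony length: the centre takes the state covering the most
#' non-missing tips (polymorphic tips count toward every state in their
#' set), and each uncovered tip costs one step.
#' @noRd
max_steps_per_character <- function(m) {
  eff <- effective_cells(m)
  vapply(seq_len(m$nchar), function(j) {
    keep <- !m$missing[, j]
    sets <- eff[keep, j]
    if (!length(sets)) return(0L)
    cover <- vapply(m$observed[[j]], function(s)
      sum(vapply(sets, function(x) s %in% x, TRUE)), 0L)
    length(sets) - max(cover)
  }, 0L)
}

#' Ensemble consistency, retention, and rescaled consistency indices
#'
#' For character i with observed steps s_i ([fitch_length()]), minimum steps
#' m_i, and star-tree maximum g_i: CI = sum(m)/sum(s), RI =
#' (sum(g)-sum(s))/(sum(g)-sum(m)), RC = CI x RI. A character is parsimony-
#' uninformative when g_i = m_i (its fit is identical on every tree); the
#' `_excl` variants exclude such characters. Both CI variants, and RC under
#' both conventions, are reported; `rc` follows `rc_convention`.
#'
#' @param tree rooted `phylo` or `timetree`.
#' @param m a `char_matrix`.
#' @param rc_convention CI variant used for the headline `rc`:
#'   `"all"` (default) or `"excl"`.
#' @return object of class `ensemble_indices`: per-character table plus
#'   `ci_all`, `ci_excl`, `ri`, `rc`, `rc_all`, `rc_excl`. Indices are `NA`
#'   when their denominator is zero.
#' @export
ensemble_indices <- function(tree, m, rc_convention = c("all", "excl")) {
  rc_convention <- match.arg(rc_convention)
  s <- fitch_length(tree, m)$per_character
  mi <- min_steps_per_character(m)
  gi <- max_steps_per_character(m)
  informative <- gi > mi
  safe_div <- function(a, b) if (abs(b) < .Machine$double.eps) NA_real_ else a / b
  ci_all <- safe_div(sum(mi), sum(s))
  ci_excl <- safe_div(sum(mi[informative]), sum(s[informative]))
  ri <- safe_div(sum(gi) - sum(s), sum(gi) - sum(mi))
  per_char <- data.frame(
    character = seq_len(m$nchar), steps = s, min_steps = mi, max_steps = gi,
    informative = informative,
    ci = ifelse(s > 0, mi / s, NA_real_),
    ri = ifelse(gi > mi, (gi - s) / (gi - mi), NA_real_))
  structure(list(per_character = per_char, tree_length = sum(s),
                 ci_all = ci_all, ci_excl = ci_excl, ri = ri,
                 rc_all = ci_all * ri, rc_excl = ci_excl * ri,
                 rc = (if (rc_convention == "all") ci_all else ci_excl) * ri,
                 rc_convention = rc_convention),
            class = "ensemble_indices")
}

#' @export
print.ensemble_indices <- function(x, ...) {
  cat("Tree length:", x$tree_length, "steps over",
      nrow(x$per_character), "characters\n")
  cat(sprintf("  CI (all) = %.4f; CI (excl. uninformative) = %.4f\n",
              x$ci_all, x$ci_excl))
  cat(sprintf("  RI = %.4f; RC = %.4f (convention: CI_%s x RI)\n",
              x$ri, x$rc, x$rc_convention))
  invisible(x)
}
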