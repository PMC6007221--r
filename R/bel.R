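# Minimal BEL Script dialect: simple terms a()/p()/g()/r()/bp()/path()/complex()
# with NS:Name arguments, eight relations, SET/UNSET of Citation, Evidence and
# Subgraph. Nested terms (modifications, variants, composite arguments) are
# outside the dialect and raise parse errors (or are counted in lenient mode).

REL_KEYWORDS <- c(
  increases = "increases",
  directlyIncreases = "directly_increases",
  directly_increases = "directly_increases",
  decreases = "decreases",
  directlyDecreases = "directly_decreases",
  directly_decreases = "directly_decreases",
  regulates = "regulates",
  association = "association",
  positiveCorrelation = "positive_correlation",
  positive_correlation = "positive_correlation",
  negativeCorrelation = "negative_correlation",
  negative_correlation = "negative_correlation"
)

REL_EMIT <- c(
  increases = "increases", directly_increases = "directlyIncreases",
  decreases = "decreases", directly_decreases = "directlyDecreases",
  regulates = "regulates", association = "association",
  positive_correlation = "positiveCorrelation",
  negative_correlation = "negativeCorrelation"
)

# Drop a trailing `#` comment, honouring double-quoted regions.
strip_bel_comment <- function(line) {
  chars <- strsplit(line, "", fixed = TRUE)[[1]]
  inq <- FALSE
  for (i in seq_along(chars)) {
    if (chars[i] == '"') inq <- !inq
    else if (chars[i] == "#" && !inq) return(substr(line, 1, i - 1))
  }
  line
}

# Whitespace tokenizer honouring double-quoted regions. NULL on unterminated
# quote.
bel_tokens <- function(line) {
  chars <- strsplit(line, "", fixed = TRUE)[[1]]
  toks <- character(0)
  cur <- character(0)
  inq <- FALSE
  for (ch in chars) {
    if (ch == '"') {
      inq <- !inq
      cur <- c(cur, ch)
    } else if (!inq && ch %in% c(" ", "\t")) {
      if (length(cur)) {
        toks <- c(toks, paste(cur, collapse = ""))
        cur <- character(0)
      }
    } else {
      cur <- c(cur, ch)
    }
  }
  if (inq) return(NULL)
  if (length(cur)) toks <- c(toks, paste(cur, collapse = ""))
  toks
}

#' Parse a single BEL term string
#'
#' @param tok term string, e.g. `p(HGNC:SCN1A)` or
#'   `bp(GO:"neuronal action potential")`.
#' @return list with fields `func`, `namespace`, `name`.
#' @export
parse_bel_term <- function(tok) {
  m <- regexec("^([A-Za-z]+)\\((.*)\\)$", tok)
  parts <- regmatches(tok, m)[[1]]
  if (length(parts) != 3 || !(parts[2] %in% BEL_FUNCTIONS)) {
    cn_stop("comorbnet_parse_error", "malformed or unsupported term '%s'", tok)
  }
  func <- names(BEL_FUNCTIONS)[BEL_FUNCTIONS == parts[2]]
  inner <- parts[3]
  if (grepl("[(),]", gsub('"[^"]*"', "", inner))) {
    cn_stop("comorbnet_parse_error",
            "nested or multi-argument term '%s' is outside the supported dialect", tok)
  }
  im <- regexec('^([A-Za-z0-9_]+):(.+)$', inner)
  ip <- regmatches(inner, im)[[1]]
  if (length(ip) != 3) {
    cn_stop("comorbnet_parse_error", "term '%s' must use NS:Name form", tok)
  }
  name <- ip[3]
  if (grepl('^"', name)) {
    if (!grepl('^"[^"]+"$', name)) {
      cn_stop("comorbnet_parse_error", "malformed quoted name in term '%s'", tok)
    }
    name <- substr(name, 2, nchar(name) - 1)
  } else if (!grepl("^[A-Za-z0-9_.-]+$", name)) {
    cn_stop("comorbnet_parse_error", "unquoted name with special characters in '%s'", tok)
  }
  list(func = func, namespace = ip[2], name = name)
}

# Extract the quoted strings of a value like "X" or {"A", "B"}.
quoted_items <- function(value) {
  value <- trimws(value)
  if (grepl('^\\{.*\\}$', value) || grepl('^".*"$', value)) {
    items <- regmatches(value, gregexpr('"[^"]*"', value))[[1]]
    if (length(items)) return(substr(items, 2, nchar(items) - 1))
  }
  NULL
}

#' Parse a document in the minimal BEL Script dialect
#'
#' Supported lines: `#` comments, `SET Citation = {"Type", "Identifier"}`
#' (a middle name entry is tolerated), `SET Evidence = "..."`,
#' `SET Subgraph = "Label"` or `= {"A", "B"}`, the corresponding `UNSET`s
#' (and `UNSET ALL`), and statements `term relation term`. Every statement
#' yields one relation carrying the citation and subgraph annotations active
#' at its line.
#'
#' @param text a single string (newline-separated) or a character vector of
#'   lines.
#' @param lenient if `TRUE`, lines outside the dialect (including statements
#'   lacking a citation) are skipped and reported in the `skipped` attribute
#'   of the result instead of raising errors.
#' @return a [knowledge_assembly()]; in lenient mode it carries an attribute
#'   `skipped`, a data.frame with columns `line` and `reason`.
#' @export
parse_bel_subset <- function(text, lenient = FALSE) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }
  citation <- NULL
  evidence <- NA_character_
  subgraphs <- character(0)
  stmts <- list()
  skipped <- list()

  fail <- function(i, msg, ...) {
    msg <- sprintf(msg, ...)
    if (lenient) {
      skipped[[length(skipped) + 1L]] <<- data.frame(
        line = i, reason = msg, stringsAsFactors = FALSE)
      return(FALSE)
    }
    cn_stop("comorbnet_parse_error", "line %d: %s", i, msg)
  }

  for (i in seq_along(lines)) {
    line <- trimws(strip_bel_comment(lines[i]))
    if (!nzchar(line)) next

    if (grepl("^SET\\s+", line)) {
      m <- regexec("^SET\\s+([A-Za-z_]+)\\s*=\\s*(.+)$", line)
      parts <- regmatches(line, m)[[1]]
      if (length(parts) != 3) {
        fail(i, "malformed SET line")
        next
      }
      key <- parts[2]
      items <- quoted_items(parts[3])
      if (key == "Citation") {
        if (is.null(items) || length(items) < 2 || length(items) > 3 ||
            !nzchar(items[length(items)])) {
          fail(i, "Citation must be {\"Type\", \"Identifier\"} with a non-empty identifier")
          next
        }
        citation <- c(items[1], items[length(items)])
      } else if (key == "Evidence" || key == "SupportingText") {
        if (is.null(items) || length(items) != 1) {
          fail(i, "Evidence must be a single quoted string")
          next
        }
        evidence <- items[1]
      } else if (key == "Subgraph") {
        if (is.null(items) || !length(items) || any(!nzchar(items))) {
          fail(i, "Subgraph must be a quoted label or a list of labels")
          next
        }
        subgraphs <- sort(unique(items))
      } else {
        fail(i, sprintf("unsupported annotation '%s'", key))
      }
      next
    }

    if (grepl("^UNSET\\b", line)) {
      key <- trimws(sub("^UNSET\\s*", "", line))
      if (key %in% c("ALL", "")) {
        citation <- NULL; evidence <- NA_character_; subgraphs <- character(0)
      } else if (key == "Citation") citation <- NULL
      else if (key %in% c("Evidence", "SupportingText")) evidence <- NA_character_
      else if (key == "Subgraph") subgraphs <- character(0)
      else fail(i, sprintf("unsupported UNSET target '%s'", key))
      next
    }

    if (grepl("^DEFINE\\b", line)) {
      fail(i, "DEFINE directives are outside the supported dialect")
      next
    }

    toks <- bel_tokens(line)
    if (is.null(toks)) {
      fail(i, "unterminated quote")
      next
    }
    if (length(toks) != 3) {
      fail(i, "statement must be 'term relation term'")
      next
    }
    if (!(toks[2] %in% names(REL_KEYWORDS))) {
      fail(i, sprintf("unknown relation keyword '%s'", toks[2]))
      next
    }
    if (is.null(citation)) {
      if (lenient) {
        fail(i, "statement before any SET Citation")
        next
      }
      cn_stop("comorbnet_missing_citation",
              "line %d: statement before any SET Citation", i)
    }
    sub_term <- tryCatch(parse_bel_term(toks[1]), comorbnet_parse_error = identity)
    obj_term <- tryCatch(parse_bel_term(toks[3]), comorbnet_parse_error = identity)
    if (inherits(sub_term, "condition") || inherits(obj_term, "condition")) {
      bad <- if (inherits(sub_term, "condition")) sub_term else obj_term
      if (lenient) {
        fail(i, conditionMessage(bad))
        next
      }
      cn_stop("comorbnet_parse_error", "line %d: %s", i, conditionMessage(bad))
    }
    stmts[[length(stmts) + 1L]] <- list(
      subject = sub_term, object = obj_term,
      relation = unname(REL_KEYWORDS[toks[2]]),
      citation_type = citation[1], citation_id = citation[2],
      evidence = evidence, subgraphs = subgraphs, line = i
    )
  }

  assembly <- if (length(stmts)) {
    ent_of <- function(field) {
      data.frame(
        func = vapply(stmts, function(s) s[[field]]$func, character(1)),
        namespace = vapply(stmts, function(s) s[[field]]$namespace, character(1)),
        name = vapply(stmts, function(s) s[[field]]$name, character(1)),
        stringsAsFactors = FALSE
      )
    }
    subj <- ent_of("subject")
    obj <- ent_of("object")
    relations <- data.frame(
      subject = entity_key(subj$func, subj$namespace, subj$name),
      relation = vapply(stmts, `[[`, character(1), "relation"),
      object = entity_key(obj$func, obj$namespace, obj$name),
      citation_type = vapply(stmts, `[[`, character(1), "citation_type"),
      citation_id = vapply(stmts, `[[`, character(1), "citation_id"),
      evidence = vapply(stmts, `[[`, character(1), "evidence"),
      line = vapply(stmts, `[[`, integer(1), "line"),
      stringsAsFactors = FALSE
    )
    relations$subgraphs <- I(lapply(stmts, `[[`, "subgraphs"))
    knowledge_assembly(rbind(subj, obj), relations)
  } else {
    knowledge_assembly()
  }
  if (lenient) {
    attr(assembly, "skipped") <- if (length(skipped)) {
      do.call(rbind, skipped)
    } else {
      data.frame(line = integer(0), reason = character(0), stringsAsFactors = FALSE)
    }
  }
  assembly
}

#' @param path path to a BEL Script file.
#' @rdname parse_bel_subset
#' @export
read_bel <- function(path, lenient = FALSE) {
  if (!file.exists(path)) cn_stop("comorbnet_io_error", "cannot read BEL file '%s'", path)
  parse_bel_subset(readLines(path, warn = FALSE), lenient = lenient)
}

#' Serialize an assembly to the minimal BEL Script dialect
#'
#' Emits relations in row order, inserting `SET`/`UNSET` lines whenever the
#' active citation, evidence or subgraph annotations change. Re-parsing the
#' output recovers a structurally identical assembly (up to line numbers and
#' inventory labels that annotate no relation, which have no BEL
#' representation in this dialect).
#'
#' @param assembly a [knowledge_assembly()].
#' @param path optional file path; when given the script is written there.
#' @return character vector of script lines (invisibly when `path` is given).
#' @export
serialize_bel <- function(assembly, path = NULL) {
  stopifnot(inherits(assembly, "knowledge_assembly"))
  rel <- assembly$relations
  out <- c("# BEL subset document", "")
  cur_cit <- c(NA_character_, NA_character_)
  cur_ev <- NA_character_
  cur_sub <- character(0)
  for (i in seq_len(nrow(rel))) {
    cit <- c(rel$citation_type[i], rel$citation_id[i])
    if (!identical(cit, cur_cit)) {
      out <- c(out, sprintf('SET Citation = {"%s", "%s"}', cit[1], cit[2]))
      cur_cit <- cit
    }
    ev <- rel$evidence[i]
    if (!identical(ev, cur_ev)) {
      out <- c(out,
               if (is.na(ev)) "UNSET Evidence" else sprintf('SET Evidence = "%s"', ev))
      cur_ev <- ev
    }
    sub <- rel$subgraphs[[i]]
    if (!identical(sub, cur_sub)) {
      out <- c(out, if (!length(sub)) {
        "UNSET Subgraph"
      } else if (length(sub) == 1L) {
        sprintf('SET Subgraph = "%s"', sub)
      } else {
        sprintf('SET Subgraph = {%s}', paste(sprintf('"%s"', sub), collapse = ", "))
      })
      cur_sub <- sub
    }
    out <- c(out, paste(rel$subject[i], REL_EMIT[rel$relation[i]], rel$object[i]))
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
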