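#' Serialise a knowledge base to a plain list
#'
#' @param kb a [knowledge_base()].
#' @return a nested list with sections `intervals`, `rules`, `edges`,
#'   `formulas`, `implausible_zeros` suitable for YAML/JSON.
#' @export
kb_to_list <- function(kb) {
  list(
    intervals = lapply(kb$scheme$intervals, function(d) {
      lapply(seq_len(nrow(d)), function(i) list(
        label = d$label[i], lower = d$lower[i], upper = d$upper[i],
        lower_closed = d$lower_closed[i], upper_closed = d$upper_closed[i]
      ))
    }),
    rules = lapply(kb$rules, function(r) list(
      literals = lapply(r$literals, function(l)
        list(feature = l$feature, op = l$op, threshold = l$threshold)),
      consequent = r$consequent
    )),
    edges = lapply(seq_len(nrow(kb$structure$edges)), function(i)
      list(from = kb$structure$edges$from[i], to = kb$structure$edges$to[i])),
    formulas = lapply(kb$formulas, function(f) list(
      name = f$name, intercept = f$intercept,
      coefficients = as.list(f$coefficients)
    )),
    implausible_zeros = kb$implausible_zero_features
  )
}

#' Rebuild a knowledge base from its plain-list form
#'
#' @param x a list as produced by [kb_to_list()].
#' @param schema a [feature_schema()].
#' @return a [knowledge_base()].
#' @export
kb_from_list <- function(x, schema = pima_schema()) {
  # Inf round-trips as the string ".inf"/"Inf" in YAML/JSON; coerce back.
  num <- function(v) if (is.character(v)) as.numeric(sub("^\\.", "", v)) else as.numeric(v)
  scheme <- discretisation_scheme(lapply(x$intervals, function(rows) {
    do.call(rbind, lapply(rows, function(r)
      .iv(r$label, num(r$lower), num(r$upper),
          isTRUE(r$lower_closed), isTRUE(r$upper_closed))))
  }))
  rules <- lapply(x$rules, function(r)
    logic_rule(lapply(r$literals, function(l)
      threshold_literal(l$feature, l$op, num(l$threshold))),
      consequent = r$consequent))
  edges <- do.call(rbind, lapply(x$edges, function(e) c(e$from, e$to)))
  nodes <- unique(c(edges[, 1], edges[, 2], schema$outcome))
  structure <- causal_structure(nodes, edges, outcome = schema$outcome)
  formulas <- lapply(x$formulas, function(f)
    composite_formula(f$name, num(f$intercept),
                      stats::setNames(vapply(f$coefficients, num, numeric(1)),
                                      names(f$coefficients))))
  knowledge_base(scheme, rules, structure, formulas,
                 unlist(x$implausible_zeros), schema = schema)
}

#' Write a knowledge base to YAML or JSON
#'
#' The file format is chosen from the extension (`.yaml`/`.yml` or `.json`).
#'
#' @param kb a [knowledge_base()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_knowledge <- function(kb, path) {
  x <- kb_to_list(kb)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else stop("unsupported knowledge-base file extension: ", path)
  invisible(path)
}

#' Read a knowledge base from YAML or JSON
#'
#' @param path input file path.
#' @param schema a [feature_schema()].
#' @return a [knowledge_base()].
#' @export
read_knowledge <- function(path, schema = pima_schema()) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    x <- yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = FALSE)
  } else stop("unsupported knowledge-base file extension: ", path)
  kb_from_list(x, schema = schema)
}
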