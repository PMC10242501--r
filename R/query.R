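# MXQL: an XML cross-tabulation query dialect. A query declares distribution
# rows, columns and filters — each a constraint tree over catalog attributes —
# plus the ID level (patient / appointment / examination) at which constraints
# must co-occur and at which distinct matches are counted.

CONTENT_OPERATORS <- c("equals", "not_equals", "contains", "regex",
                       "lt", "le", "gt", "ge", "between")
ID_LEVELS <- c("PID", "AID", "EID")

#' Build an attribute constraint
#'
#' @param ext_id external ID of the catalog attribute.
#' @param domain catalog project/terminology of the attribute.
#' @param op content operator (`r paste(CONTENT_OPERATORS, collapse = ", ")`)
#'   or `NULL` for presence-only matching.
#' @param content desired content; for `between` the lower bound.
#' @param content2 upper bound for `between`.
#' @param display_name optional label used for result rows/columns.
#' @param negated match IDs with *no* value satisfying the constraint.
#' @return an `mx_attribute` node.
#' @export
mx_attribute <- function(ext_id, domain = "ris", op = NULL, content = NULL,
                         content2 = NULL, display_name = NULL, negated = FALSE) {
  if (!is.null(op) && !op %in% CONTENT_OPERATORS)
    abort_validation(paste0("unknown content operator '", op, "'"))
  if (identical(op, "between") && (is.null(content) || is.null(content2)))
    abort_validation("'between' needs both bounds")
  structure(list(ext_id = ext_id, domain = domain, op = op,
                 content = content, content2 = content2,
                 display_name = display_name, negated = isTRUE(negated)),
            class = "mx_attribute")
}

#' Logical groups of query nodes
#'
#' `mx_and`/`mx_or` combine attribute constraints (or nested groups) with set
#' intersection/union over the IDs matching each child.
#'
#' @param ... child nodes (`mx_attribute` or `mx_group`); at least one.
#' @param display_name optional label.
#' @return an `mx_group` node.
#' @export
mx_and <- function(..., display_name = NULL) mx_group("and", list(...), display_name)

#' @rdname mx_and
#' @export
mx_or <- function(..., display_name = NULL) mx_group("or", list(...), display_name)

mx_group <- function(op, children, display_name = NULL) {
  if (length(children) == 0L) abort_validation("logical group must be non-empty")
  structure(list(op = op, children = children, display_name = display_name),
            class = "mx_group")
}

#' Build an MXQL query
#'
#' @param rows,cols non-empty lists of query nodes (a bare node is wrapped).
#' @param filters list of query nodes applied to every cell.
#' @param id_level `"PID"`, `"AID"` or `"EID"`.
#' @return an `mx_query`.
#' @export
mx_query <- function(rows, cols, filters = list(), id_level) {
  as_nodes <- function(x) {
    if (inherits(x, c("mx_attribute", "mx_group"))) list(x) else x
  }
  rows <- as_nodes(rows); cols <- as_nodes(cols); filters <- as_nodes(filters)
  if (length(rows) == 0L || length(cols) == 0L)
    abort_validation("query needs at least one row and one column")
  if (missing(id_level) || !id_level %in% ID_LEVELS)
    abort_validation("query needs an ID level (PID, AID or EID)")
  structure(list(rows = rows, cols = cols, filters = filters,
                 id_level = id_level), class = "mx_query")
}

node_label <- function(node) {
  if (!is.null(node$display_name)) return(node$display_name)
  if (inherits(node, "mx_attribute")) {
    lbl <- node$ext_id
    if (!is.null(node$content)) lbl <- paste0(lbl, "=", node$content)
    return(lbl)
  }
  paste0(node$op, "(", paste(vapply(node$children, node_label, character(1)),
                             collapse = ","), ")")
}

# Value matching -----------------------------------------------------------

numericish <- function(data_type) data_type %in% c("Number", "DateTime")

# normalize one side of a comparison to a sortable scalar
comparable <- function(x, data_type) {
  if (data_type == "DateTime") as.numeric(parse_timestamp(x))
  else suppressWarnings(as.numeric(x))
}

#' Does a stored value satisfy a constraint?
#'
#' Operator semantics: `equals` is exact (string equality for
#' Text/SingleChoice/Boolean, numeric equality for Number, instant equality
#' for DateTime); `contains` is case-insensitive substring; `regex` must match
#' the full value; `lt/le/gt/ge/between` compare numerically or by instant
#' (`between` closed on both ends). Without a desired content, presence of any
#' value suffices. The `negated` flag is *not* applied here — negation is a
#' document-level complement, handled in [ids_matching()].
#'
#' @param constraint an [mx_attribute()].
#' @param values character vector of stored canonical values.
#' @param data_type the attribute's data type (scalar or vector along values).
#' @return logical vector.
#' @export
match_value <- function(constraint, values, data_type) {
  op <- constraint$op
  if (is.null(op) || is.null(constraint$content))
    return(rep(TRUE, length(values)))  # presence-only
  dt <- if (length(data_type) == 1L) rep(data_type, length(values)) else data_type
  if (op %in% c("lt", "le", "gt", "ge", "between") && !all(numericish(dt)))
    abort_validation(paste0("operator '", op,
                            "' needs a Number or DateTime attribute"))
  want <- constraint$content
  switch(op,
    equals = {
      num <- numericish(dt)
      out <- logical(length(values))
      if (any(num)) out[num] <- comparable(values[num], dt[which(num)[1]]) ==
          comparable(want, dt[which(num)[1]])
      out[!num] <- values[!num] == want
      out & !is.na(out)
    },
    not_equals = {
      eq <- match_value(modifyList(constraint, list(op = "equals")), values, data_type)
      !eq
    },
    contains = stringr::str_detect(stringr::str_to_lower(values),
                                   stringr::fixed(stringr::str_to_lower(want))),
    regex = {
      hit <- stringr::str_detect(values, stringr::regex(paste0("^(?:", want, ")$")))
      hit & !is.na(hit)
    },
    lt = cmp_op(values, dt, want, `<`),
    le = cmp_op(values, dt, want, `<=`),
    gt = cmp_op(values, dt, want, `>`),
    ge = cmp_op(values, dt, want, `>=`),
    between = {
      v <- comparable(values, dt[1])
      lo <- comparable(constraint$content, dt[1])
      hi <- comparable(constraint$content2, dt[1])
      out <- v >= lo & v <= hi
      out & !is.na(out)
    },
    abort_validation(paste0("unknown content operator '", op, "'"))
  )
}

cmp_op <- function(values, dt, want, f) {
  out <- f(comparable(values, dt[1]), comparable(want, dt[1]))
  out & !is.na(out)
}

# XML parse / serialize ----------------------------------------------------

#' Parse an MXQL document
#'
#' The dialect: root `Query`; `IDFilter` with a `filterIDType` property (PID,
#' AID or EID, required); `DistributionRow` / `DistributionColumn` /
#' `DistributionFilter` elements each wrapping one node; nodes are `Attribute`
#' elements (properties `domain`, `extID`, `contentOperator`,
#' `desiredContent`, `desiredContentMax` for between, `displayName`,
#' `not="true"`) or `And` / `Or` groups of nodes.
#'
#' @param xml MXQL as a string, file path or `xml2` document.
#' @return an [mx_query()].
#' @export
parse_mxql <- function(xml) {
  doc <- if (inherits(xml, "xml_document")) xml else xml2::read_xml(xml)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "Query")
    abort_validation("root element must be Query")
  parse_node <- function(el) {
    nm <- xml2::xml_name(el)
    if (nm == "Attribute") {
      a <- function(key) {
        v <- xml2::xml_attr(el, key)
        if (is.na(v)) NULL else v
      }
      op <- a("contentOperator")
      if (!is.null(op) && !op %in% CONTENT_OPERATORS)
        abort_validation(paste0("unknown content operator '", op, "'"))
      ext <- a("extID")
      if (is.null(ext)) abort_validation("Attribute element without extID")
      mx_attribute(ext_id = ext, domain = a("domain") %||% "ris", op = op,
                   content = a("desiredContent"),
                   content2 = a("desiredContentMax"),
                   display_name = a("displayName"),
                   negated = identical(a("not"), "true"))
    } else if (nm %in% c("And", "Or")) {
      kids <- purrr::map(xml2::xml_children(el), parse_node)
      mx_group(tolower(nm), kids,
               display_name = {
                 d <- xml2::xml_attr(el, "displayName")
                 if (is.na(d)) NULL else d
               })
    } else {
      abort_validation(paste0("unknown element '", nm, "' in query"))
    }
  }
  rows <- cols <- filters <- list()
  id_level <- NULL
  for (el in xml2::xml_children(root)) {
    nm <- xml2::xml_name(el)
    if (nm == "IDFilter") {
      id_level <- xml2::xml_attr(el, "filterIDType")
      if (is.na(id_level) || !id_level %in% ID_LEVELS)
        abort_validation("IDFilter needs filterIDType PID, AID or EID")
    } else if (nm %in% c("DistributionRow", "DistributionColumn",
                         "DistributionFilter")) {
      kids <- xml2::xml_children(el)
      if (length(kids) != 1L)
        abort_validation(paste0(nm, " must wrap exactly one node"))
      node <- parse_node(kids[[1]])
      if (nm == "DistributionRow") rows <- c(rows, list(node))
      else if (nm == "DistributionColumn") cols <- c(cols, list(node))
      else filters <- c(filters, list(node))
    } else if (nm == "Attribute" || nm %in% c("And", "Or")) {
      # a bare attribute acts as a row (minimal query form)
      rows <- c(rows, list(parse_node(el)))
    } else {
      abort_validation(paste0("unknown element '", nm, "' in query"))
    }
  }
  if (is.null(id_level))
    abort_validation("query is missing the IDFilter element")
  n_attr <- length(xml2::xml_find_all(root, ".//Attribute"))
  if (n_attr == 0L)
    abort_validation("query must contain at least one Attribute")
  if (length(cols) == 0L && length(rows) > 0L) {
    # a query without columns counts each row against everything
    cols <- list(mx_attribute("*", domain = "_all_", display_name = "all"))
  }
  mx_query(rows = rows, cols = cols, filters = filters, id_level = id_level)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize an MXQL query to XML
#'
#' Round-trip stable: `parse_mxql(serialize_mxql(q))` reproduces the AST.
#'
#' @param q an [mx_query()].
#' @return XML as a character string.
#' @export
serialize_mxql <- function(q) {
  doc <- xml2::xml_new_root("Query")
  idf <- xml2::xml_add_child(doc, "IDFilter")
  xml2::xml_set_attr(idf, "filterIDType", q$id_level)
  add_node <- function(parent, node) {
    if (inherits(node, "mx_attribute")) {
      el <- xml2::xml_add_child(parent, "Attribute")
      xml2::xml_set_attr(el, "domain", node$domain)
      xml2::xml_set_attr(el, "extID", node$ext_id)
      if (!is.null(node$op)) xml2::xml_set_attr(el, "contentOperator", node$op)
      if (!is.null(node$content))
        xml2::xml_set_attr(el, "desiredContent", node$content)
      if (!is.null(node$content2))
        xml2::xml_set_attr(el, "desiredContentMax", node$content2)
      if (!is.null(node$display_name))
        xml2::xml_set_attr(el, "displayName", node$display_name)
      if (isTRUE(node$negated)) xml2::xml_set_attr(el, "not", "true")
    } else {
      el <- xml2::xml_add_child(parent, if (node$op == "and") "And" else "Or")
      if (!is.null(node$display_name))
        xml2::xml_set_attr(el, "displayName", node$display_name)
      for (child in node$children) add_node(el, child)
    }
    el
  }
  for (r in q$rows) add_node(xml2::xml_add_child(doc, "DistributionRow"), r)
  for (cc in q$cols) add_node(xml2::xml_add_child(doc, "DistributionColumn"), cc)
  for (f in q$filters) add_node(xml2::xml_add_child(doc, "DistributionFilter"), f)
  as.character(doc)
}

# Evaluation ---------------------------------------------------------------

eval_node <- function(ix, wh, node, level) {
  if (inherits(node, "mx_attribute")) {
    if (identical(node$domain, "_all_")) return(index_universe(ix, level))
    return(ids_matching(ix, wh, node, level))
  }
  sets <- lapply(node$children, eval_node, ix = ix, wh = wh, level = level)
  if (node$op == "and") Reduce(intersect, sets) else Reduce(union, sets)
}

#' Evaluate an MXQL query against an index
#'
#' Cell (i, j) counts the distinct IDs at the query's level matching row i,
#' column j and every filter simultaneously — the co-occurrence is at the ID
#' level: a patient matches `modality = Rö and region = Abdomen` if both occur
#' anywhere in the patient's records, not necessarily in the same examination
#' (run an EID-level query for same-examination co-occurrence).
#'
#' @param ix a [build_index()] result.
#' @param wh the [warehouse()] behind the index.
#' @param q an [mx_query()].
#' @return a `result_table`: integer matrix with row/column labels.
#' @export
evaluate <- function(ix, wh, q) {
  level <- q$id_level
  index_universe(ix, level)  # fail early (capability) on unsupported levels
  row_sets <- lapply(q$rows, eval_node, ix = ix, wh = wh, level = level)
  col_sets <- lapply(q$cols, eval_node, ix = ix, wh = wh, level = level)
  filt <- if (length(q$filters))
    Reduce(intersect, lapply(q$filters, eval_node, ix = ix, wh = wh,
                             level = level))
  else NULL
  cells <- matrix(0L, nrow = length(row_sets), ncol = length(col_sets))
  for (i in seq_along(row_sets)) {
    ri <- row_sets[[i]]
    if (!is.null(filt)) ri <- intersect(ri, filt)
    for (j in seq_along(col_sets))
      cells[i, j] <- length(intersect(ri, col_sets[[j]]))
  }
  result_table(cells,
               row_labels = vapply(q$rows, node_label, character(1)),
               col_labels = vapply(q$cols, node_label, character(1)),
               id_level = level)
}
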