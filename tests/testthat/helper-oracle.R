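# Brute-force query oracle over the flat synthetic RIS table, independent of
# the warehouse/index/query engine. Shared by the test suite and by
# scripts/acceptance.R.

# Attribute metadata of the synthetic export (mirrors its configuration file).
oracle_attr_meta <- function(with_pid = TRUE) {
  m <- data.frame(
    ext = c("PID", "CID", "REQUEST", "START", "END", "REPORT", "MOD", "LOC",
            "DEPT", "DEVICE", "QUEST", "STAY", "INSUR"),
    col = c("PatientID", "CID", "RequestDate", "StartDate", "EndDate",
            "ReportDate", "Modality", "Localization", "Department", "Device",
            "Question", "StayType", "Insurance"),
    type = c("Text", "Text", "DateTime", "DateTime", "DateTime", "DateTime",
             "SingleChoice", "SingleChoice", "SingleChoice", "SingleChoice",
             "SingleChoice", "Boolean", "Boolean"),
    stringsAsFactors = FALSE)
  if (!with_pid) m <- m[m$ext != "PID", ]
  m
}

# Long value frame from the flat table: one row per non-empty cell, with ids
# and the value as the import canonicalizes it (modality remapping, boolean
# tokens, ISO timestamps). Exam ids use the synthesized <CID>#<ordinal> form.
oracle_frame <- function(table, meta = oracle_attr_meta("PatientID" %in% names(table))) {
  ord <- stats::ave(seq_len(nrow(table)), table$CID, FUN = seq_along)
  eid <- paste0(table$CID, "#", ord)
  pid <- if ("PatientID" %in% names(table)) table$PatientID else NA_character_
  modmap <- c(XR = "Rö", MR = "MRI", US = "Sono")
  out <- list()
  for (i in seq_len(nrow(meta))) {
    v <- as.character(table[[meta$col[i]]])
    keep <- nzchar(v)
    val <- v[keep]
    if (meta$col[i] == "Modality")
      val <- ifelse(val %in% names(modmap), modmap[val], val)
    if (meta$type[i] == "Boolean")
      val <- ifelse(tolower(val) %in% c("1", "true", "ja", "yes"), "true",
             ifelse(tolower(val) %in% c("0", "false", "nein", "no"), "false", NA))
    out[[i]] <- data.frame(
      ext = meta$ext[i], type = meta$type[i],
      pid = pid[keep], aid = table$CID[keep], eid = eid[keep],
      value = val, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

oracle_match <- function(op, content, content2, values, type) {
  if (is.null(op) || is.null(content)) return(rep(TRUE, length(values)))
  comp <- function(x) if (type == "DateTime")
    as.numeric(as.POSIXct(sub("T", " ", x), tz = "UTC")) else
    suppressWarnings(as.numeric(x))
  nafalse <- function(x) x & !is.na(x)
  switch(op,
    equals = if (type %in% c("Number", "DateTime"))
      nafalse(comp(values) == comp(content)) else values == content,
    not_equals = if (type %in% c("Number", "DateTime"))
      !nafalse(comp(values) == comp(content)) else values != content,
    contains = grepl(tolower(content), tolower(values), fixed = TRUE),
    regex = nafalse(grepl(paste0("^(?:", content, ")$"), values, perl = TRUE)),
    lt = nafalse(comp(values) < comp(content)),
    le = nafalse(comp(values) <= comp(content)),
    gt = nafalse(comp(values) > comp(content)),
    ge = nafalse(comp(values) >= comp(content)),
    between = nafalse(comp(values) >= comp(content) &
                      comp(values) <= comp(content2)),
    stop("oracle: unknown operator ", op))
}

oracle_ids <- function(frame, node, level) {
  col <- c(PID = "pid", AID = "aid", EID = "eid")[[level]]
  universe <- unique(frame[[col]][!is.na(frame[[col]])])
  rec <- function(node) {
    if (inherits(node, "mx_attribute")) {
      sub <- frame[frame$ext == node$ext_id, , drop = FALSE]
      hit <- oracle_match(node$op, node$content, node$content2,
                          sub$value, sub$type[1])
      ids <- unique(sub[[col]][hit])
      ids <- ids[!is.na(ids)]
      if (isTRUE(node$negated)) setdiff(universe, ids) else ids
    } else {
      sets <- lapply(node$children, rec)
      if (node$op == "and") Reduce(intersect, sets) else Reduce(union, sets)
    }
  }
  rec(node)
}

# Full cross-tab by brute force; returns an integer matrix.
oracle_table <- function(frame, q) {
  rows <- lapply(q$rows, oracle_ids, frame = frame, level = q$id_level)
  cols <- lapply(q$cols, oracle_ids, frame = frame, level = q$id_level)
  filt <- if (length(q$filters))
    Reduce(intersect, lapply(q$filters, oracle_ids, frame = frame,
                             level = q$id_level)) else NULL
  m <- matrix(0L, length(rows), length(cols))
  for (i in seq_along(rows)) {
    ri <- rows[[i]]
    if (!is.null(filt)) ri <- intersect(ri, filt)
    for (j in seq_along(cols)) m[i, j] <- length(intersect(ri, cols[[j]]))
  }
  m
}

# Random query generator over the synthetic export's attributes -------------

random_constraint <- function(frame, meta) {
  i <- sample(nrow(meta), 1)
  ext <- meta$ext[i]; type <- meta$type[i]
  vals <- frame$value[frame$ext == ext]
  if (length(vals) == 0) vals <- "x"
  pick <- function() sample(vals, 1)
  op <- NULL; content <- NULL; content2 <- NULL
  if (type %in% c("SingleChoice", "Text")) {
    op <- sample(c("equals", "not_equals", "contains", "regex", NA), 1,
                 prob = c(.4, .15, .2, .15, .1))
    if (is.na(op)) op <- NULL
    if (!is.null(op)) {
      v <- pick()
      content <- switch(op,
        contains = substr(v, 1, max(1, nchar(v) - 1)),
        regex = paste0(gsub("([\\^$.|?*+()\\[\\]{}\\\\])", "\\\\\\1", v,
                            perl = TRUE), "|zzz"),
        v)
    }
  } else if (type == "Boolean") {
    op <- "equals"; content <- sample(c("true", "false"), 1)
  } else {  # DateTime
    op <- sample(c("lt", "le", "gt", "ge", "between"), 1)
    a <- pick(); b <- pick()
    if (op == "between") {
      content <- min(a, b); content2 <- max(a, b)
    } else content <- a
  }
  mx_attribute(ext, "ris", op, content, content2,
               negated = stats::runif(1) < 0.15)
}

random_node <- function(frame, meta, depth = 0) {
  if (depth >= 2 || stats::runif(1) < 0.6) return(random_constraint(frame, meta))
  k <- sample(2:3, 1)
  kids <- replicate(k, random_node(frame, meta, depth + 1), simplify = FALSE)
  if (stats::runif(1) < 0.5) do.call(mx_and, kids) else do.call(mx_or, kids)
}

random_query <- function(frame, meta, with_pid = TRUE) {
  levels <- if (with_pid) c("PID", "AID", "EID") else c("AID", "EID")
  mx_query(
    rows = replicate(sample(1:3, 1), random_node(frame, meta), simplify = FALSE),
    cols = replicate(sample(1:2, 1), random_node(frame, meta), simplify = FALSE),
    filters = if (stats::runif(1) < 0.4)
      replicate(sample(1:2, 1), random_node(frame, meta), simplify = FALSE)
      else list(),
    id_level = sample(levels, 1))
}
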