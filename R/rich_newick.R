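# Rich Newick dialect: per-node field triple name:length:theta, a fourth
# field gamma on reticulation (hybrid) edges, hybrid nodes written twice
# under a shared "#H<i>" tag, and an optional leading "[theta]" giving the
# population mutation rate of the infinite branch above the root, e.g.
#   [0.006](((A:1:0.005)X#H1:1:0.005:0.7,B:2:0.005):1:0.005,(X#H1:1:0.005:0.3,C:2:0.005):1:0.005);

#' Parse a rich Newick network string
#'
#' @param text a single network string (see the dialect description above).
#' @return A validated `"phylo_network"`.
#' @details The two occurrences of each `#H` tag are fused into one
#'   reticulation node; the fourth colon field of each hybrid-edge
#'   occurrence is its inheritance probability.  Errors on malformed
#'   strings, duplicate leaf labels, and gamma pairs not summing to 1
#'   (tolerance 1e-9).
#' @export
read_rich_newick <- function(text) {
  s <- gsub("[[:space:]]", "", text)
  env <- new.env(parent = emptyenv())
  env$s <- strsplit(s, "")[[1]]
  env$i <- 1L
  env$kind <- integer(0); env$label <- character(0)
  env$ep <- integer(0); env$ec <- integer(0)
  env$el <- numeric(0); env$eth <- numeric(0); env$eg <- numeric(0)
  env$hyb <- list()      # tag -> node id
  env$had_children <- logical(0)

  peek <- function() if (env$i <= length(env$s)) env$s[env$i] else ""
  advance <- function() env$i <- env$i + 1L
  expect <- function(ch) {
    if (peek() != ch)
      stop("malformed rich Newick: expected '", ch, "' at position ", env$i)
    advance()
  }
  read_number <- function() {
    j <- env$i
    while (env$i <= length(env$s) && grepl("[-+0-9.eE]", env$s[env$i])) advance()
    if (env$i == j) stop("malformed rich Newick: expected a number at position ", j)
    as.numeric(paste(env$s[j:(env$i - 1L)], collapse = ""))
  }
  read_label <- function() {
    j <- env$i
    while (env$i <= length(env$s) && !grepl("[](),:;[]", env$s[env$i])) advance()
    if (env$i == j) "" else paste(env$s[j:(env$i - 1L)], collapse = "")
  }
  new_node <- function(label) {
    env$kind <- c(env$kind, NODE_TREE)
    env$label <- c(env$label, label)
    env$had_children <- c(env$had_children, FALSE)
    length(env$kind)
  }
  # returns list(id, len, theta, gamma)
  parse_clade <- function() {
    kids <- list()
    if (peek() == "(") {
      advance()
      repeat {
        kids[[length(kids) + 1L]] <- parse_clade()
        if (peek() == ",") { advance(); next }
        break
      }
      expect(")")
    }
    lab <- read_label()
    len <- NA_real_; th <- NA_real_; g <- NA_real_
    if (peek() == ":") { advance(); len <- read_number() }
    if (peek() == ":") { advance(); th <- read_number() }
    if (peek() == ":") { advance(); g <- read_number() }
    if (grepl("#", lab)) {
      tag <- sub(".*#", "#", lab)
      if (!is.null(env$hyb[[tag]])) {
        id <- env$hyb[[tag]]
        if (length(kids) && env$had_children[id])
          stop("malformed rich Newick: hybrid tag ", tag,
               " has children in both occurrences")
      } else {
        id <- new_node(lab)
        env$hyb[[tag]] <- id
      }
      env$kind[id] <- NODE_RETIC
    } else {
      id <- new_node(lab)
    }
    for (k in kids) {
      env$ep <- c(env$ep, id); env$ec <- c(env$ec, k$id)
      env$el <- c(env$el, k$len); env$eth <- c(env$eth, k$theta)
      env$eg <- c(env$eg, k$gamma)
      env$had_children[id] <- TRUE
    }
    list(id = id, len = len, theta = th, gamma = g)
  }

  root_theta <- NA_real_
  if (peek() == "[") {
    advance()
    root_theta <- read_number()
    expect("]")
  }
  top <- parse_clade()
  expect(";")
  if (env$i <= length(env$s))
    stop("malformed rich Newick: trailing characters after ';'")
  # leaves: nodes that never had children and are not hybrids
  env$kind[!env$had_children & env$kind != NODE_RETIC] <- NODE_LEAF
  net <- phylo_network(env$kind, env$label, env$ep, env$ec,
                       env$el, env$eth, env$eg, root_theta = root_theta)
  diag <- validate_network(net)
  fatal <- grep("^(cycle|labels|gamma|root)", diag$violations, value = TRUE)
  if (length(fatal))
    stop("invalid network in rich Newick string: ",
         paste(fatal, collapse = "; "))
  net
}

#' Write a network in the rich Newick dialect
#'
#' Inverse of [read_rich_newick()] up to isomorphism and child order.
#'
#' @param net a `"phylo_network"`.
#' @return A single string.
#' @export
write_rich_newick <- function(net) {
  rets <- net$ret_index
  tag <- character(n_nodes(net))
  for (i in seq_along(rets)) {
    lab <- net$label[rets[i]]
    tag[rets[i]] <- if (grepl("#", lab)) lab else paste0("I", rets[i], "#H", i)
  }
  emitted <- logical(n_nodes(net))
  fields <- function(eidx) {
    out <- ""
    if (!is.na(net$elen[eidx])) {
      out <- paste0(":", format_num(net$elen[eidx]))
      if (!is.na(net$etheta[eidx])) {
        out <- paste0(out, ":", format_num(net$etheta[eidx]))
        if (!is.na(net$egamma[eidx]))
          out <- paste0(out, ":", format_num(net$egamma[eidx]))
      }
    }
    out
  }
  rec <- function(v, eidx) {
    if (net$kind[v] == NODE_RETIC) {
      if (emitted[v]) return(paste0(tag[v], fields(eidx)))
      emitted[v] <<- TRUE
      es <- out_edge_idx(net, v)
      body <- paste0("(", paste(vapply(es, function(e)
        rec(net$echild[e], e), ""), collapse = ","), ")")
      return(paste0(body, tag[v], fields(eidx)))
    }
    if (net$kind[v] == NODE_LEAF)
      return(paste0(net$label[v], if (!is.na(eidx)) fields(eidx) else ""))
    es <- out_edge_idx(net, v)
    body <- paste0("(", paste(vapply(es, function(e)
      rec(net$echild[e], e), ""), collapse = ","), ")")
    paste0(body, net$label[v], if (!is.na(eidx)) fields(eidx) else "")
  }
  pre <- if (!is.na(net$root_theta))
    paste0("[", format_num(net$root_theta), "]") else ""
  paste0(pre, rec(net$root, NA_integer_), ";")
}
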