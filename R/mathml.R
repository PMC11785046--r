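# Content MathML <-> R expressions.
#
# SBML kinetic laws, rules, and SED-ML data generators carry content MathML.
# We map the subset needed for kinetic ODE models onto R language objects so
# that renaming, substitution, and vectorized evaluation reuse R's own
# machinery. The time csymbol becomes the reserved name `time`.

MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
TIME_URL <- "http://www.sbml.org/sbml/symbols/time"

mathml_binary_ops <- c(plus = "+", minus = "-", times = "*", divide = "/",
                       power = "^")
mathml_relations <- c(lt = "<", leq = "<=", gt = ">", geq = ">=",
                      eq = "==", neq = "!=")
mathml_unary_funs <- c(exp = "exp", ln = "log", sin = "sin", cos = "cos",
                       tan = "tan", abs = "abs", floor = "floor",
                       ceiling = "ceiling", sinh = "sinh", cosh = "cosh",
                       tanh = "tanh", arcsin = "asin", arccos = "acos",
                       arctan = "atan")

# node: the <math> element or any content element below it
parse_mathml <- function(node) {
  if (inherits(node, "xml_document")) node <- xml2::xml_root(node)
  if (xml2::xml_name(node) == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1) {
      vk_stop("unsupported-mathml", "math element must have one child")
    }
    return(parse_mathml(kids[[1]]))
  }
  nm <- xml2::xml_name(node)
  kids <- xml2::xml_children(node)
  if (nm == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (nm == "cn") return(parse_mathml_cn(node))
  if (nm == "csymbol") {
    url <- xml2::xml_attr(node, "definitionURL")
    if (identical(url, TIME_URL) || grepl("symbols/time$", url %||% "")) {
      return(as.name("time"))
    }
    if (grepl("symbols/avogadro$", url %||% "")) return(6.02214179e23)
    vk_stop("unsupported-mathml", paste("csymbol", url))
  }
  if (nm == "true") return(TRUE)
  if (nm == "false") return(FALSE)
  if (nm == "pi") return(pi)
  if (nm == "exponentiale") return(exp(1))
  if (nm == "infinity") return(Inf)
  if (nm == "notanumber") return(NaN)
  if (nm == "piecewise") return(parse_mathml_piecewise(node))
  if (nm != "apply") vk_stop("unsupported-mathml", paste("element", nm))

  op <- kids[[1]]
  opname <- xml2::xml_name(op)
  args <- lapply(kids[-1], parse_mathml)
  if (opname %in% names(mathml_binary_ops)) {
    rop <- mathml_binary_ops[[opname]]
    if (opname == "minus" && length(args) == 1) {
      return(call("-", args[[1]]))
    }
    if (length(args) < 2) {
      if (opname == "plus" && length(args) <= 1) {
        return(if (length(args) == 1) args[[1]] else 0)
      }
      if (opname == "times" && length(args) <= 1) {
        return(if (length(args) == 1) args[[1]] else 1)
      }
      vk_stop("unsupported-mathml", paste("arity of", opname))
    }
    expr <- args[[1]]
    for (a in args[-1]) expr <- call(rop, expr, a)
    return(expr)
  }
  if (opname %in% names(mathml_relations)) {
    if (length(args) != 2) vk_stop("unsupported-mathml", "relation arity")
    return(call(mathml_relations[[opname]], args[[1]], args[[2]]))
  }
  if (opname %in% names(mathml_unary_funs)) {
    if (length(args) != 1) vk_stop("unsupported-mathml", "function arity")
    return(call(mathml_unary_funs[[opname]], args[[1]]))
  }
  if (opname == "log") {
    base <- 10
    deg <- xml2::xml_find_first(node, "./*[local-name()='logbase']")
    if (!inherits(deg, "xml_missing")) {
      base <- parse_mathml(xml2::xml_child(deg))
      args <- lapply(kids[-(1:2)], parse_mathml)
    }
    return(call("/", call("log", args[[1]]), call("log", base)))
  }
  if (opname == "root") {
    deg <- xml2::xml_find_first(node, "./*[local-name()='degree']")
    degree <- 2
    if (!inherits(deg, "xml_missing")) {
      degree <- parse_mathml(xml2::xml_child(deg))
      args <- lapply(kids[-(1:2)], parse_mathml)
    }
    return(call("^", args[[1]], call("/", 1, degree)))
  }
  if (opname %in% c("and", "or")) {
    rop <- if (opname == "and") "&" else "|"
    expr <- args[[1]]
    for (a in args[-1]) expr <- call(rop, expr, a)
    return(expr)
  }
  if (opname == "not") return(call("!", args[[1]]))
  if (opname == "ci") {
    # user-defined function application (SBML functionDefinition)
    fname <- trimws(xml2::xml_text(op))
    return(as.call(c(as.name(fname), args)))
  }
  vk_stop("unsupported-mathml", paste("operator", opname))
}

parse_mathml_cn <- function(node) {
  type <- xml2::xml_attr(node, "type") %||% "real"
  if (is.na(type)) type <- "real"
  if (type %in% c("e-notation", "rational")) {
    # parts are separated by <sep/> elements, not whitespace
    parts <- character(0)
    cur <- ""
    for (k in xml2::xml_contents(node)) {
      if (xml2::xml_name(k) == "sep") {
        parts <- c(parts, cur)
        cur <- ""
      } else {
        cur <- paste0(cur, xml2::xml_text(k))
      }
    }
    parts <- trimws(c(parts, cur))
    a <- as.numeric(parts[1]); b <- as.numeric(parts[2])
    return(if (type == "e-notation") a * 10^b else a / b)
  }
  as.numeric(trimws(xml2::xml_text(node)))
}

parse_mathml_piecewise <- function(node) {
  pieces <- xml2::xml_find_all(node, "./*[local-name()='piece']")
  otherwise <- xml2::xml_find_first(node, "./*[local-name()='otherwise']")
  args <- list()
  for (p in pieces) {
    kids <- xml2::xml_children(p)
    args <- c(args, parse_mathml(kids[[1]]), parse_mathml(kids[[2]]))
  }
  if (!inherits(otherwise, "xml_missing")) {
    args <- c(args, parse_mathml(xml2::xml_child(otherwise)))
  }
  as.call(c(as.name("vk_piecewise"), args))
}

#' Vectorized piecewise evaluation (content MathML `piecewise`)
#'
#' Arguments come in (value, condition) pairs, optionally followed by a final
#' `otherwise` value; the first true condition wins, NA where none holds and
#' no otherwise is given.
#' @param ... alternating values and conditions, optional trailing default.
#' @return numeric vector.
#' @export
vk_piecewise <- function(...) {
  args <- list(...)
  npairs <- length(args) %/% 2
  has_other <- length(args) %% 2 == 1
  n <- max(vapply(args, length, 1L))
  out <- rep(if (has_other) 0 else NA_real_, n)
  if (has_other) out <- rep_len(as.numeric(args[[length(args)]]), n)
  taken <- rep(FALSE, n)
  for (i in seq_len(npairs)) {
    val <- rep_len(as.numeric(args[[2 * i - 1]]), n)
    cond <- rep_len(as.logical(args[[2 * i]]), n) & !taken
    out[cond] <- val[cond]
    taken <- taken | cond
  }
  out
}

# Serialize an R expression (from parse_mathml, or built in code) back to a
# content-MathML <math> element, returned as an xml2 node tree.
mathml_to_xml <- function(expr) {
  doc <- xml2::xml_new_root("math", xmlns = MATHML_NS)
  mathml_append(doc, expr)
  doc
}

mathml_append <- function(parent, expr) {
  if (is.name(expr)) {
    nm <- as.character(expr)
    if (nm == "time") {
      node <- xml2::xml_add_child(parent, "csymbol", encoding = "text",
                                  definitionURL = TIME_URL)
      xml2::xml_set_text(node, " time ")
    } else {
      node <- xml2::xml_add_child(parent, "ci")
      xml2::xml_set_text(node, paste0(" ", nm, " "))
    }
    return(invisible(parent))
  }
  if (is.numeric(expr) || is.logical(expr)) {
    if (isTRUE(expr)) { xml2::xml_add_child(parent, "true"); return(invisible(parent)) }
    if (isFALSE(expr)) { xml2::xml_add_child(parent, "false"); return(invisible(parent)) }
    node <- xml2::xml_add_child(parent, "cn")
    val <- as.numeric(expr)
    if (is.finite(val) && val == round(val) && abs(val) < 1e15) {
      if (val != trunc(val) || grepl("e", format(val))) {
        xml2::xml_set_text(node, paste0(" ", format(val, digits = 17), " "))
      } else {
        xml2::xml_set_attr(node, "type", "integer")
        xml2::xml_set_text(node, paste0(" ", format(val, scientific = FALSE), " "))
      }
    } else {
      xml2::xml_set_text(node, paste0(" ", format(val, digits = 17), " "))
    }
    return(invisible(parent))
  }
  if (!is.call(expr)) vk_stop("unsupported-mathml", "cannot serialize node")
  op <- as.character(expr[[1]])
  args <- as.list(expr)[-1]
  apply_node <- xml2::xml_add_child(parent, "apply")
  emit_op <- function(tag) xml2::xml_add_child(apply_node, tag)
  rev_bin <- stats::setNames(names(mathml_binary_ops), mathml_binary_ops)
  rev_rel <- stats::setNames(names(mathml_relations), mathml_relations)
  rev_fun <- stats::setNames(names(mathml_unary_funs), mathml_unary_funs)
  if (op %in% names(rev_bin)) {
    emit_op(rev_bin[[op]])
  } else if (op %in% names(rev_rel)) {
    emit_op(rev_rel[[op]])
  } else if (op %in% names(rev_fun)) {
    emit_op(rev_fun[[op]])
  } else if (op == "(") {
    xml2::xml_remove(apply_node)
    return(mathml_append(parent, args[[1]]))
  } else if (op == "vk_piecewise") {
    xml2::xml_remove(apply_node)
    pw <- xml2::xml_add_child(parent, "piecewise")
    npairs <- length(args) %/% 2
    for (i in seq_len(npairs)) {
      piece <- xml2::xml_add_child(pw, "piece")
      mathml_append(piece, args[[2 * i - 1]])
      mathml_append(piece, args[[2 * i]])
    }
    if (length(args) %% 2 == 1) {
      other <- xml2::xml_add_child(pw, "otherwise")
      mathml_append(other, args[[length(args)]])
    }
    return(invisible(parent))
  } else {
    # user-defined function call
    ci <- xml2::xml_add_child(apply_node, "ci")
    xml2::xml_set_text(ci, paste0(" ", op, " "))
  }
  for (a in args) mathml_append(apply_node, a)
  invisible(parent)
}

# All symbol names appearing in an expression.
expr_symbols <- function(expr) {
  if (is.name(expr)) return(as.character(expr))
  if (is.call(expr)) {
    op <- expr[[1]]
    syms <- unlist(lapply(as.list(expr)[-1], expr_symbols))
    if (is.name(op) &&
        !(as.character(op) %in% c(mathml_binary_ops, mathml_relations,
                                  mathml_unary_funs, "&", "|", "!", "(",
                                  "vk_piecewise", "log", "exp"))) {
      syms <- c(as.character(op), syms)
    }
    return(unique(syms %||% character(0)))
  }
  character(0)
}

# Substitute symbols by expressions (named list), leaving others untouched.
expr_substitute <- function(expr, env_list) {
  if (is.name(expr)) {
    nm <- as.character(expr)
    if (nm %in% names(env_list)) return(env_list[[nm]])
    return(expr)
  }
  if (is.call(expr)) {
    out <- as.list(expr)
    for (i in seq_along(out)[-1]) out[[i]] <- expr_substitute(out[[i]], env_list)
    return(as.call(out))
  }
  expr
}
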