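# Safe single-variable formula mini-language used for background correction,
# calibration and manual model right-hand sides. User text is parsed to an
# explicit AST and interpreted by a closed recursive evaluator: no base-R
# eval() of user input, so formulas cannot touch the filesystem, environment
# variables, or any name outside the declared vocabulary.

formula_functions <- c("min", "max", "mean", "median",
                       "log", "log2", "log10", "exp", "sqrt", "abs")
formula_aggregates <- c("min", "max", "mean", "median")
reserved_names <- c(formula_functions, "y", "x")

# ---- tokenizer ---------------------------------------------------------

formula_tokenize <- function(text) {
  n <- nchar(text)
  toks <- list()
  i <- 1L
  while (i <= n) {
    rest <- substring(text, i)
    if (grepl("^\\s", rest)) {
      i <- i + attr(regexpr("^\\s+", rest), "match.length")
      next
    }
    m <- regexpr("^(\\d+\\.?\\d*|\\.\\d+)([eE][+-]?\\d+)?", rest)
    if (m == 1L) {
      len <- attr(m, "match.length")
      toks[[length(toks) + 1L]] <- list(type = "num",
                                        value = as.numeric(substr(rest, 1L, len)),
                                        pos = i)
      i <- i + len
      next
    }
    m <- regexpr("^[A-Za-z][A-Za-z0-9_.]*", rest)
    if (m == 1L) {
      len <- attr(m, "match.length")
      toks[[length(toks) + 1L]] <- list(type = "name",
                                        value = substr(rest, 1L, len), pos = i)
      i <- i + len
      next
    }
    ch <- substr(rest, 1L, 1L)
    type <- switch(ch,
      "+" = , "-" = , "*" = , "/" = , "^" = "op",
      "(" = "lparen", ")" = "rparen",
      "[" = "lbracket", "]" = "rbracket",
      ":" = "colon", "," = "comma",
      "~" = , "?" = "tilde",
      NULL)
    if (is.null(type)) {
      stop(formula_error(text, i, paste0("unexpected character '", ch, "'")),
           call. = FALSE)
    }
    toks[[length(toks) + 1L]] <- list(type = type, value = ch, pos = i)
    i <- i + 1L
  }
  toks[[length(toks) + 1L]] <- list(type = "end", value = "", pos = n + 1L)
  toks
}

formula_error <- function(text, pos, msg) {
  paste0("formula syntax error at position ", pos, ": ", msg, "\n  ",
         text, "\n  ", strrep(" ", pos - 1L), "^")
}

# ---- recursive-descent parser ------------------------------------------

new_parser <- function(text) {
  env <- new.env(parent = emptyenv())
  env$text <- text
  env$toks <- formula_tokenize(text)
  env$i <- 1L
  env
}

p_peek <- function(p) p$toks[[p$i]]
p_next <- function(p) {
  t <- p$toks[[p$i]]
  p$i <- p$i + 1L
  t
}
p_expect <- function(p, type, what) {
  t <- p_next(p)
  if (t$type != type) {
    stop(formula_error(p$text, t$pos, paste0("expected ", what)), call. = FALSE)
  }
  t
}

parse_additive <- function(p) {
  node <- parse_multiplicative(p)
  while (p_peek(p)$type == "op" && p_peek(p)$value %in% c("+", "-")) {
    op <- p_next(p)$value
    node <- list(type = "bin", op = op, lhs = node, rhs = parse_multiplicative(p))
  }
  node
}

parse_multiplicative <- function(p) {
  node <- parse_unary(p)
  while (p_peek(p)$type == "op" && p_peek(p)$value %in% c("*", "/")) {
    op <- p_next(p)$value
    node <- list(type = "bin", op = op, lhs = node, rhs = parse_unary(p))
  }
  node
}

parse_unary <- function(p) {
  if (p_peek(p)$type == "op" && p_peek(p)$value == "-") {
    p_next(p)
    return(list(type = "neg", arg = parse_unary(p)))
  }
  parse_power(p)
}

parse_power <- function(p) {
  node <- parse_postfix(p)
  if (p_peek(p)$type == "op" && p_peek(p)$value == "^") {
    p_next(p)
    node <- list(type = "bin", op = "^", lhs = node, rhs = parse_unary(p))
  }
  node
}

parse_postfix <- function(p) {
  node <- parse_primary(p)
  while (p_peek(p)$type == "lbracket") {
    p_next(p)
    from <- parse_additive(p)
    to <- NULL
    if (p_peek(p)$type == "colon") {
      p_next(p)
      to <- parse_additive(p)
    }
    p_expect(p, "rbracket", "']'")
    node <- list(type = "index", target = node, from = from, to = to)
  }
  node
}

parse_primary <- function(p) {
  t <- p_next(p)
  if (t$type == "num") return(list(type = "num", value = t$value))
  if (t$type == "name") {
    if (p_peek(p)$type == "lparen") {
      if (!t$value %in% formula_functions) {
        stop(formula_error(p$text, t$pos,
                           paste0("unknown function '", t$value, "'; allowed: ",
                                  paste(formula_functions, collapse = ", "))),
             call. = FALSE)
      }
      p_next(p)
      args <- list(parse_additive(p))
      while (p_peek(p)$type == "comma") {
        p_next(p)
        args[[length(args) + 1L]] <- parse_additive(p)
      }
      p_expect(p, "rparen", "')'")
      if (length(args) != 1L) {
        stop(formula_error(p$text, t$pos,
                           paste0("'", t$value, "' takes exactly one argument")),
             call. = FALSE)
      }
      return(list(type = "call", fn = t$value, args = args))
    }
    return(list(type = "var", name = t$value))
  }
  if (t$type == "lparen") {
    node <- parse_additive(p)
    p_expect(p, "rparen", "')'")
    return(node)
  }
  stop(formula_error(p$text, t$pos, "expected a number, name or '('"),
       call. = FALSE)
}

ast_free_vars <- function(ast) {
  switch(ast$type,
    num = character(),
    var = ast$name,
    neg = ast_free_vars(ast$arg),
    bin = union(ast_free_vars(ast$lhs), ast_free_vars(ast$rhs)),
    call = unique(unlist(lapply(ast$args, ast_free_vars))),
    index = unique(c(ast_free_vars(ast$target), ast_free_vars(ast$from),
                     if (!is.null(ast$to)) ast_free_vars(ast$to)))
  )
}

#' Parse a well or model formula
#'
#' Well-mode formulas (background correction, calibration) are expressions
#' over the measure vector `y` and runtime vector `x`, e.g. `"y - min(y)"` or
#' `"y - mean(y[1:5])"`. Model-mode formulas have the shape
#' `"y ~ <expression over x and parameters>"`, e.g.
#' `"y ~ a - (a - w0) * exp(-k * x)"`; every free name other than `x` becomes
#' a model parameter. The vocabulary is closed: literals, `y`/`x`/parameters,
#' `+ - * / ^`, unary minus, 1-based inclusive indexing `y[a]`/`y[a:b]`, and
#' the functions min, max, mean, median, log, log2, log10, exp, sqrt, abs.
#' Nothing else parses, so formulas cannot execute arbitrary code.
#'
#' @param text Formula string. In model mode both `~` and `?` are accepted as
#'   the separator and canonicalized to `~`.
#' @param mode `"well"` or `"model"`.
#' @return An object of class `gc_formula` with fields `ast`, `mode`, `text`
#'   and, in model mode, `params` (ordered parameter names).
#' @examples
#' parse_formula("y - min(y)", "well")
#' parse_formula("y ~ a - (a - w0) * exp(-k * x)", "model")
#' @export
parse_formula <- function(text, mode = c("well", "model")) {
  mode <- match.arg(mode)
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop("formula text must be a nonempty string", call. = FALSE)
  }
  if (mode == "model") {
    m <- regexpr("^\\s*y\\s*[~?]", text)
    if (m != 1L) {
      stop("model formula must have the form 'y ~ <expression>'", call. = FALSE)
    }
    rhs_text <- substring(text, m + attr(m, "match.length"))
    p <- new_parser(rhs_text)
    ast <- parse_additive(p)
    t <- p_peek(p)
    if (t$type != "end") {
      stop(formula_error(rhs_text, t$pos, "unexpected trailing input"), call. = FALSE)
    }
    vars <- ast_free_vars(ast)
    params <- setdiff(vars, "x")
    if ("y" %in% vars) {
      stop("'y' may not appear on the right-hand side of a model formula",
           call. = FALSE)
    }
    if (length(params) == 0L) {
      stop("model formula must have at least one parameter", call. = FALSE)
    }
    bad <- intersect(params, reserved_names)
    if (length(bad)) {
      stop("reserved name(s) used as parameter: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    out <- list(ast = ast, mode = mode, params = params,
                text = paste0("y ~", rhs_text))
  } else {
    p <- new_parser(text)
    ast <- parse_additive(p)
    t <- p_peek(p)
    if (t$type != "end") {
      stop(formula_error(text, t$pos, "unexpected trailing input"), call. = FALSE)
    }
    vars <- ast_free_vars(ast)
    bad <- setdiff(vars, c("y", "x"))
    if (length(bad)) {
      stop("well formulas may only use 'y' and 'x'; found: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    out <- list(ast = ast, mode = mode, params = character(), text = text)
  }
  structure(out, class = "gc_formula")
}

#' @export
print.gc_formula <- function(x, ...) {
  cat("<", x$mode, " formula> ", x$text, "\n", sep = "")
  if (length(x$params)) cat("parameters:", paste(x$params, collapse = ", "), "\n")
  invisible(x)
}

# ---- evaluator ---------------------------------------------------------

eval_ast <- function(ast, env) {
  switch(ast$type,
    num = ast$value,
    var = {
      v <- env[[ast$name]]
      if (is.null(v)) stop("unbound variable '", ast$name, "'", call. = FALSE)
      v
    },
    neg = -eval_ast(ast$arg, env),
    bin = {
      l <- eval_ast(ast$lhs, env)
      r <- eval_ast(ast$rhs, env)
      switch(ast$op,
        "+" = l + r, "-" = l - r, "*" = l * r, "/" = l / r, "^" = l^r)
    },
    call = {
      a <- eval_ast(ast$args[[1L]], env)
      switch(ast$fn,
        min = min(a), max = max(a), mean = mean(a),
        median = stats::median(a),
        log = safe_log(a, base = exp(1)),
        log2 = safe_log(a, base = 2),
        log10 = safe_log(a, base = 10),
        exp = exp(a), sqrt = sqrt(a), abs = abs(a))
    },
    index = {
      target <- eval_ast(ast$target, env)
      from <- eval_ast(ast$from, env)
      to <- if (is.null(ast$to)) from else eval_ast(ast$to, env)
      if (length(from) != 1L || length(to) != 1L ||
          from != round(from) || to != round(to)) {
        stop("slice indices must be scalar integers", call. = FALSE)
      }
      if (from < 1L || to > length(target) || from > to) {
        stop("slice [", from, ":", to, "] out of bounds for length ",
             length(target), call. = FALSE)
      }
      target[from:to]
    }
  )
}

safe_log <- function(a, base) {
  bad <- !is.na(a) & a <= 0
  if (any(bad)) {
    warning("log of nonpositive value(s); returning NA", call. = FALSE)
    a[bad] <- NA_real_
  }
  log(a, base = base)
}

#' Evaluate a well formula on one well's measures
#'
#' Applies a parsed well-mode formula to the measure vector `y` and runtime
#' vector `x`. Aggregates (min, max, mean, median) reduce to a scalar and
#' broadcast; slices are 1-based inclusive; the output always has the length
#' of the input.
#'
#' @param formula A `gc_formula` from [parse_formula()] (or a string, parsed
#'   in well mode).
#' @param y Numeric measure vector.
#' @param x Numeric runtime vector, same length as `y`.
#' @return Numeric vector of length `length(y)`.
#' @examples
#' eval_well_formula("y - min(y)", y = c(0.10, 0.30), x = c(0, 1))
#' @export
eval_well_formula <- function(formula, y, x = seq_along(y)) {
  if (is.character(formula)) formula <- parse_formula(formula, "well")
  stopifnot(inherits(formula, "gc_formula"), formula$mode == "well")
  if (length(y) < 1L || length(x) != length(y)) {
    stop("y and x must have equal length >= 1", call. = FALSE)
  }
  out <- eval_ast(formula$ast, list(y = as.numeric(y), x = as.numeric(x)))
  rep_len(as.numeric(out), length(y))
}

#' Evaluate a model formula at given parameter values
#'
#' @param formula A model-mode `gc_formula`.
#' @param x Numeric runtime vector.
#' @param params Named list/vector covering every model parameter.
#' @return Numeric vector of model predictions, length `length(x)`.
#' @export
eval_model_formula <- function(formula, x, params) {
  if (is.character(formula)) formula <- parse_formula(formula, "model")
  stopifnot(inherits(formula, "gc_formula"), formula$mode == "model")
  params <- as.list(params)
  miss <- setdiff(formula$params, names(params))
  if (length(miss)) {
    stop("missing parameter value(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  env <- c(list(x = as.numeric(x)), lapply(params, as.numeric))
  rep_len(as.numeric(eval_ast(formula$ast, env)), length(x))
}

#' Parse starting values for a manual model fit
#'
#' Accepts comma-separated `name = value` pairs, e.g.
#' `"a = 1,w0 = 0.5, k = 0.00003"`. Scientific notation is accepted; order is
#' preserved.
#'
#' @param text The comma-separated pairs.
#' @param params Optional character vector of allowed parameter names; names
#'   outside it are rejected.
#' @return Named numeric vector.
#' @examples
#' parse_start_values("a = 1,w0 = 0.5, k = 0.00003")
#' @export
parse_start_values <- function(text, params = NULL) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop("start values must be a nonempty string", call. = FALSE)
  }
  parts <- strsplit(text, ",", fixed = TRUE)[[1L]]
  out <- numeric(0)
  for (part in parts) {
    m <- regexec("^\\s*([A-Za-z][A-Za-z0-9_.]*)\\s*=\\s*([-+]?(\\d+\\.?\\d*|\\.\\d+)([eE][+-]?\\d+)?)\\s*$",
                 part)[[1L]]
    if (m[1L] == -1L) {
      stop("malformed start value '", trimws(part),
           "'; expected 'name = value'", call. = FALSE)
    }
    nm <- regmatches(part, list(m))[[1L]][2L]
    val <- as.numeric(regmatches(part, list(m))[[1L]][3L])
    if (nm %in% names(out)) {
      stop("duplicate start value for '", nm, "'", call. = FALSE)
    }
    if (!is.null(params) && !nm %in% params) {
      stop("'", nm, "' is not a model parameter; expected one of: ",
           paste(params, collapse = ", "), call. = FALSE)
    }
    out[nm] <- val
  }
  out
}

# ---- rendering and differentiation -------------------------------------

# Convert an AST to an R language object over the same vocabulary. Used to
# hand model right-hand sides to stats::D for analytic derivatives and to
# print canonical formula text; never applied to unvalidated input.
ast_to_lang <- function(ast) {
  switch(ast$type,
    num = ast$value,
    var = as.name(ast$name),
    neg = call("-", ast_to_lang(ast$arg)),
    bin = call(ast$op, ast_to_lang(ast$lhs), ast_to_lang(ast$rhs)),
    call = {
      arg <- ast_to_lang(ast$args[[1L]])
      switch(ast$fn,
        log2 = call("/", call("log", arg), log(2)),
        log10 = call("/", call("log", arg), log(10)),
        as.call(c(as.name(ast$fn), list(arg))))
    },
    index = {
      idx <- if (is.null(ast$to)) ast_to_lang(ast$from) else
        call(":", ast_to_lang(ast$from), ast_to_lang(ast$to))
      call("[", ast_to_lang(ast$target), idx)
    }
  )
}

# TRUE when the AST is a smooth closed-form expression stats::D can
# differentiate (no aggregates, indexing, abs or median).
ast_differentiable <- function(ast) {
  switch(ast$type,
    num = TRUE,
    var = TRUE,
    neg = ast_differentiable(ast$arg),
    bin = ast_differentiable(ast$lhs) && ast_differentiable(ast$rhs),
    call = ast$fn %in% c("log", "log2", "log10", "exp", "sqrt") &&
      ast_differentiable(ast$args[[1L]]),
    index = FALSE
  )
}
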