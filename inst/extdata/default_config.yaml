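# Default preprocessing configuration.
#
# stopwords: small English function-word list used for the discovery token
#   stream only; the matching stream (term counting, vocabulary size) keeps
#   every word so that multiword terms with function-word interiors
#   ("men who have sex with men") remain matchable.
# symbol_map: surface forms carrying symbols, rewritten to word phrases
#   BEFORE tokenization so the symbol is not lost to punctuation stripping.
# plural_exceptions: words never singularized / pluralized (s-final acronyms
#   and mass nouns that a trailing-s rule would mangle).
stopwords:
  - the
  - a
  - an
  - and
  - or
  - of
  - in
  - on
  - to
  - for
  - with
  - by
  - at
  - from
  - as
  - is
  - are
  - was
  - were
  - be
  - been
  - being
  - that
  - this
  - these
  - those
  - it
  - its
  - but
  - not
  - no
  - we
  - our
  - they
  - their
  - he
  - his
  - she
  - her
  - you
  - your
  - i
  - am
  - do
  - does
  - did
  - have
  - has
  - had
  - who
  - whom
  - which
  - what
  - will
  - would
  - can
  - could
  - may
  - might
  - than
  - then
  - there
  - here
  - when
  - where
  - how
  - all
  - any
  - each
  - such
  - so
  - if
  - into
  - about
  - between
  - among
  - during
  - after
  - before
  - over
  - under
  - per
  - also
  - more
  - most
  - other
  - some
  - both
  - through
symbol_map:
  "hiv+": "hiv positive"
  "hiv-": "hiv negative"
  "hiv/aids": "hiv aids"
plural_exceptions:
  - aids
  - msm
  - sms
  - hiv
  - men
  - women
  - people
  - children
  - series
  - species
  - analysis
  - diabetes
  - herpes
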