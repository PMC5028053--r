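# clinical-safe stop-word list: articles, copulas, prepositions, pronouns,
# conjunctions. negation words (no, not, without) are intentionally absent.
a
an
the
is
are
was
were
am
be
been
being
has
have
had
of
in
on
at
to
for
with
by
from
as
and
or
but
if
that
this
these
those
it
its
he
she
his
her
their
they
than
then
there
which
who
whom
while
during
into
onto
upon
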