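the
a
an
and
or
of
to
in
is
was
it
for
on
with
that
this
at
by
be
very
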